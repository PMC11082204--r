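#' Network variants
#'
#' @return Character vector of the recognized architecture names.
#' @export
variant_names <- function() {
  c("DBSACaps", "DBCaps", "DBSA", "DBNet", "HybridCaps", "SpectralCaps",
    "SpatialCaps", "DBSACapsWithRec1", "DBSACapsWithRec2", "DBSACapsWithRec3")
}

#' Build a dual-branch selective-attention capsule network
#'
#' Constructs an untrained network of the requested variant. `DBSACaps` is
#' the full model: a spectral branch of three depth-only 3-D convolutions
#' (band trace 150 -> 72 -> 33 -> 1, 128 output channels), a spatial branch
#' (one full-depth 150 x 1 x 1 spectral collapse, then two padded 3 x 3
#' convolutions, 128 channels), squeeze-and-excitation descriptors per
#' branch fused by a per-channel two-way softmax, a primary capsule layer
#' (64 capsule types x 8 dimensions on a 9 x 9 grid for 64 x 64 inputs,
#' with batch normalization), and 3 digit capsules of dimension 16 reached
#' by dynamic routing. The ablation variants drop the attention stage
#' (`DBCaps`), replace the capsule head with a convolution + affine
#' classifier (`DBSA`, `DBNet`), keep a single branch (`SpectralCaps`,
#' `SpatialCaps`, `HybridCaps`), or attach a reconstruction decoder
#' (`DBSACapsWithRec1/2/3`).
#'
#' @param variant one of [variant_names()].
#' @param bands number of spectral bands; the spectral stack's fixed valid
#'   convolutions require the 150-band configuration.
#' @param input_size spatial size of input patches (>= 6).
#' @param n_classes number of output classes.
#' @param routing_iters dynamic-routing iterations.
#' @param seed integer seed for weight initialization.
#' @return An object of class `dbsa_net`.
#' @examples
#' \donttest{
#' net <- dbsa_model("DBSACaps")
#' count_parameters(net)  # 7,135,312
#' }
#' @export
dbsa_model <- function(variant = "DBSACaps", bands = 150, input_size = 64,
                       n_classes = 3, routing_iters = 3, seed = 1L) {
  ptr <- net_create(variant, as.integer(bands), as.integer(input_size),
                    as.integer(input_size), as.integer(n_classes),
                    as.integer(routing_iters), as.integer(seed))
  structure(list(ptr = ptr, variant = variant, bands = as.integer(bands),
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 routing_iters = as.integer(routing_iters),
                 seed = as.integer(seed),
                 classes = DBSA_CLASSES[seq_len(n_classes)],
                 trained = FALSE, history = NULL),
            class = "dbsa_net")
}

#' Count trainable parameters
#'
#' @param model a `dbsa_net`.
#' @return The exact number of trainable scalars, as a numeric integer.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "dbsa_net"))
  net_nparams(model$ptr)
}

#' Band-depth trace of the feature-extraction branches
#'
#' Reports how the valid depth-only convolutions of the spectral branch
#' shrink the band dimension (150 -> 72 -> 33 -> 1 in the standard
#' configuration, by floor((D - d)/s) + 1 per layer) and the collapsed
#' depth of the spatial branch.
#'
#' @param model a `dbsa_net`.
#' @return List with `spectral_depths` and/or `spatial_collapse_depth`.
#' @export
branch_trace <- function(model) {
  stopifnot(inherits(model, "dbsa_net"))
  net_branch_trace(model$ptr)
}

#' Per-tensor parameter table
#'
#' @param model a `dbsa_net`.
#' @return Data frame with one row per parameter tensor (name, shape, size).
#' @export
parameter_table <- function(model) {
  stopifnot(inherits(model, "dbsa_net"))
  net_param_table(model$ptr)
}

#' @export
print.dbsa_net <- function(x, ...) {
  info <- net_info(x$ptr)
  cat(sprintf("%s network: %d bands, %dx%d input, %d classes\n", x$variant,
              x$bands, x$input_size, x$input_size, x$n_classes))
  cat(sprintf("  trainable parameters: %s\n",
              format(info$n_params, big.mark = ",")))
  if (isTRUE(info$caps_head))
    cat(sprintf("  capsule head: %d primary capsules (8-d, %dx%d grid), %d x 16-d digit capsules, %d routing iterations\n",
                info$ncaps, info$grid, info$grid, x$n_classes,
                x$routing_iters))
  else
    cat("  affine head: convolution + fully connected classifier (cross-entropy)\n")
  cat(if (x$trained) "  trained\n" else "  untrained\n")
  invisible(x)
}

#' @export
summary.dbsa_net <- function(object, ...) {
  tab <- parameter_table(object)
  module <- sub("\\..*$", "", tab$name)
  agg <- aggregate(tab$n, list(module = module), sum)
  names(agg)[2] <- "parameters"
  print(object)
  cat("\nParameters by module:\n")
  print(agg, row.names = FALSE)
  invisible(agg)
}

#' @export
coef.dbsa_net <- function(object, ...) net_get_params(object$ptr)

as_input_array <- function(model, newdata) {
  x <- if (inherits(newdata, "patch_set")) newdata$data else newdata
  d <- dim(x)
  if (length(d) == 3) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (length(d) != 4 || d[1] != model$bands || d[2] != model$input_size ||
        d[3] != model$input_size)
    stopf("input stage: expected %d x %d x %d (x n) array, got %s",
          model$bands, model$input_size, model$input_size,
          paste(d, collapse = " x "))
  x
}

#' Predict classes or class scores for patches
#'
#' Runs the network in evaluation mode (batch-normalization uses its
#' running statistics, so the output is deterministic and independent of
#' batch composition). For capsule heads the scores are digit-capsule
#' lengths in \[0, 1); for the affine-head variants they are softmax
#' probabilities. The predicted class is the argmax, ties broken toward
#' the lowest class index.
#'
#' @param object a `dbsa_net`.
#' @param newdata a `patch_set` or an array bands x s x s (x n).
#' @param type `"class"` or `"scores"`.
#' @param microbatch samples processed per internal forward pass.
#' @param ... unused.
#' @return A factor of classes, or an n x classes score matrix.
#' @export
predict.dbsa_net <- function(object, newdata, type = c("class", "scores"),
                             microbatch = 4, ...) {
  type <- match.arg(type)
  x <- as_input_array(object, newdata)
  scores <- net_predict(object$ptr, x, as.integer(microbatch))
  colnames(scores) <- object$classes
  if (type == "scores") return(scores)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' Stage-by-stage forward pass
#'
#' Exposes the intermediate representations of the network on a (small)
#' batch: branch feature maps, attention weights, the fused map, primary
#' capsules, digit capsules and final coupling coefficients.
#'
#' @param model a `dbsa_net`.
#' @param x a `patch_set` or input array.
#' @return A list of stage outputs (present stages depend on the variant).
#' @export
forward_detail <- function(model, x) {
  stopifnot(inherits(model, "dbsa_net"))
  net_forward_detail(model$ptr, as_input_array(model, x))
}

branch_map <- function(model, x, which) {
  det <- forward_detail(model, x)
  m <- det[[which]]
  if (is.null(m)) stopf("variant %s has no %s", model$variant, which)
  s <- model$input_size
  array(m, c(nrow(m), s, s, det$n))
}

#' Branch feature maps
#'
#' `spectral_branch` applies only depth-only (d x 1 x 1) convolutions, so
#' each output pixel depends on nothing but that pixel's own spectrum;
#' `spatial_branch` collapses the spectrum in one full-depth convolution
#' and then mixes space with padded 3 x 3 convolutions.
#'
#' @param model a `dbsa_net` containing the branch.
#' @param x input batch (array bands x s x s x n or `patch_set`).
#' @return Array 128 x s x s x n of branch features.
#' @export
spectral_branch <- function(model, x) branch_map(model, x, "U_spe")

#' @rdname spectral_branch
#' @export
spatial_branch <- function(model, x) branch_map(model, x, "U_spa")

#' Fused feature map after selective attention
#'
#' @inheritParams spectral_branch
#' @return Array 256 x s x s x n (or 128 for single-branch variants).
#' @export
fused_features <- function(model, x) branch_map(model, x, "V")

#' Primary capsules of a batch
#'
#' @inheritParams spectral_branch
#' @return Array 8 x n_capsules x n of squashed primary capsule vectors.
#' @export
primary_capsules <- function(model, x) {
  det <- forward_detail(model, x)
  if (is.null(det$primary)) stopf("variant %s has no capsule head", model$variant)
  u <- det$primary
  array(unlist(u), c(dim(u[[1]]), length(u)))
}

# ---------------------------------------------------------------------------
# pure functional building blocks (reference implementations in double
# precision; the C++ network is cross-checked against these in the tests)
# ---------------------------------------------------------------------------

#' Capsule squashing nonlinearity
#'
#' Maps a vector s to (|s|^2 / (1 + |s|^2)) s / |s|: direction preserved,
#' norm squashed into \[0, 1). Zero maps to zero.
#'
#' @param s a numeric vector, or a matrix whose columns are capsules.
#' @return Object of the same shape.
#' @export
squash <- function(s) {
  f <- function(v) {
    n2 <- sum(v^2)
    if (n2 == 0) return(v * 0)
    v * sqrt(n2) / (1 + n2)
  }
  if (is.matrix(s)) apply(s, 2, f) else f(s)
}

#' Capsule lengths as class scores
#'
#' @param digit_caps matrix (dims x classes) of digit-capsule vectors, or an
#'   array (dims x classes x n).
#' @return Euclidean norms: a length-classes vector or an n x classes matrix.
#' @export
class_lengths <- function(digit_caps) {
  if (is.matrix(digit_caps)) return(sqrt(colSums(digit_caps^2)))
  d <- dim(digit_caps)
  t(apply(digit_caps, 3, function(m) sqrt(colSums(m^2))))
}

#' Margin loss on capsule lengths
#'
#' Sum over classes of T_k max(0, m+ - l_k)^2 +
#' lambda (1 - T_k) max(0, l_k - m-)^2, averaged over the batch. This is the
#' network's only loss term when no reconstruction decoder is attached.
#'
#' @param lengths numeric vector of class lengths, or n x classes matrix.
#' @param true_class 1-based class index (or vector, one per row).
#' @param m_plus,m_minus,lambda_down margin constants.
#' @return A single nonnegative number.
#' @export
margin_loss <- function(lengths, true_class, m_plus = 0.9, m_minus = 0.1,
                        lambda_down = 0.5) {
  if (!is.matrix(lengths)) lengths <- matrix(lengths, nrow = 1)
  if (any(lengths < 0 | lengths > 1)) stopf("lengths must be in [0, 1]")
  true_class <- as.integer(true_class)
  if (any(true_class < 1 | true_class > ncol(lengths)))
    stopf("true_class out of range 1..%d", ncol(lengths))
  tot <- 0
  for (i in seq_len(nrow(lengths))) {
    T <- as.numeric(seq_len(ncol(lengths)) == true_class[i])
    tot <- tot + sum(T * pmax(0, m_plus - lengths[i, ])^2 +
                       lambda_down * (1 - T) *
                         pmax(0, lengths[i, ] - m_minus)^2)
  }
  tot / nrow(lengths)
}

#' Squeeze-and-excitation channel descriptor
#'
#' Global average pool over space, bottleneck affine map, rectifier,
#' expanding affine map, sigmoid — one weight per channel, all strictly in
#' (0, 1).
#'
#' @param x array channels x h x w.
#' @param W1,b1,W2,b2 the two affine maps (W1: reduced x channels,
#'   W2: channels x reduced).
#' @return Numeric vector of length channels.
#' @export
se_weight <- function(x, W1, b1, W2, b2) {
  pooled <- apply(x, 1, mean)
  h <- pmax(0, W1 %*% pooled + b1)
  z <- W2 %*% h + b2
  as.numeric(1 / (1 + exp(-z)))
}

#' Selective-attention fusion of two branch feature maps
#'
#' Applies a per-channel two-way softmax to the two branches' channel
#' descriptors and rescales each branch by its attention weight before
#' concatenating along channels. The two weights sum to one per channel.
#'
#' @param U_spe,U_spa arrays channels x h x w.
#' @param Z_spe,Z_spa channel descriptors (length channels).
#' @return List with `V` (2*channels x h x w), `att_spe`, `att_spa`.
#' @export
selective_fuse <- function(U_spe, U_spa, Z_spe, Z_spa) {
  if (!all(dim(U_spe) == dim(U_spa)))
    stopf("branch feature maps must have identical shape")
  if (length(Z_spe) != dim(U_spe)[1] || length(Z_spa) != dim(U_spa)[1])
    stopf("channel descriptors must have one entry per channel")
  att_spe <- as.numeric(1 / (1 + exp(Z_spa - Z_spe)))
  att_spa <- 1 - att_spe
  d <- dim(U_spe)
  V <- array(0, c(2 * d[1], d[2], d[3]))
  V[seq_len(d[1]), , ] <- U_spe * array(att_spe, d)
  V[d[1] + seq_len(d[1]), , ] <- U_spa * array(att_spa, d)
  list(V = V, att_spe = att_spe, att_spa = att_spa)
}

#' Dynamic routing by agreement
#'
#' Routes prediction vectors u_hat from input capsules to output capsules:
#' logits start at zero; each iteration softmax-normalizes them per input
#' capsule into coupling coefficients, forms each output as the squashed
#' coupling-weighted sum, and (before the last iteration) increases the
#' logit of agreeing pairs by the prediction--output dot product.
#'
#' @param u_hat array n_capsules x n_classes x dims of prediction vectors.
#' @param iters number of routing iterations (>= 1).
#' @return List with `v` (dims x n_classes digit capsules), `coupling`
#'   (final n_classes x n_capsules coupling coefficients) and
#'   `coupling_iters` (per-iteration couplings).
#' @export
dynamic_routing <- function(u_hat, iters = 3) {
  d <- dim(u_hat)
  if (length(d) != 3) stopf("u_hat must be n_capsules x n_classes x dims")
  if (!all(is.finite(u_hat))) stopf("non-finite prediction vectors")
  # to (n_classes*dims, n_capsules) with class-major row blocks
  uh <- matrix(0, d[2] * d[3], d[1])
  for (j in seq_len(d[2]))
    uh[(j - 1) * d[3] + seq_len(d[3]), ] <- t(u_hat[, j, ])
  out <- cpp_dynamic_routing(uh, d[2], d[3], as.integer(iters))
  out
}

# ---------------------------------------------------------------------------
# serialization
# ---------------------------------------------------------------------------

#' Save or load a network checkpoint
#'
#' A checkpoint stores the configuration (variant, band count, class names,
#' seeds), all trainable weights and the normalization running statistics;
#' the optimizer state is not retained.
#'
#' @param model a `dbsa_net`.
#' @param file path to an `.rds` file.
#' @return `load_model` returns the restored `dbsa_net`.
#' @export
save_model <- function(model, file) {
  stopifnot(inherits(model, "dbsa_net"))
  saveRDS(list(config = model[c("variant", "bands", "input_size",
                                "n_classes", "routing_iters", "seed",
                                "classes", "trained")],
               params = net_get_params(model$ptr),
               buffers = net_get_buffers(model$ptr),
               history = model$history), file)
  invisible(file)
}

#' @rdname save_model
#' @export
load_model <- function(file) {
  ck <- readRDS(file)
  cfg <- ck$config
  model <- dbsa_model(cfg$variant, cfg$bands, cfg$input_size, cfg$n_classes,
                      cfg$routing_iters, cfg$seed)
  net_set_params(model$ptr, ck$params)
  net_set_buffers(model$ptr, ck$buffers)
  model$trained <- isTRUE(cfg$trained)
  model$history <- ck$history
  model
}
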