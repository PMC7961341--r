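# The bilateral variational domain-adversarial model: two hemispheric
# beta-VAEs (independent weights), a bilateral convolutional feature
# extractor over the stacked latent codes, an emotion classifier and a
# gradient-reversal subject discriminator.  Heavy lifting is in compiled
# code; these wrappers define the module surface and inference-mode
# semantics (z := mu, running batch-norm statistics).

#' Architecture configuration
#'
#' The default configuration realizes the reference dimension chain: each
#' 3 x 64 x 32 hemisphere image is encoded by 3 strided 3x3 convolution +
#' batch-norm stages into a 64-dimensional latent code; the two codes are
#' stacked as a 2 x 64 map and mixed by two 2x2 convolution stages plus two
#' dense-128 stages into a 128-dimensional bilateral embedding; classifier
#' and discriminator share the dense 256-256-64 + softmax head layout.
#'
#' @param latent_dim Latent dimension J per hemisphere (default 64).
#' @param n_classes Number of emotion classes.
#' @param n_subjects Number of subjects (discriminator outputs).
#' @param input Input shape `c(bands, rows, cols)` per hemisphere.
#' @param enc_channels,enc_strides Channel counts and strides of the three
#'   encoder convolution stages.
#' @param enc_dense Width of the dense stage before the mean/sd heads.
#' @param ext_channels Channels of the two bilateral 2x2 convolution stages.
#' @param ext_dense Width of the two dense extractor stages; this is the
#'   bilateral embedding dimension.
#' @param head_dense Widths of the three dense stages in each head.
#' @param hemi `"both"`, `"left"` or `"right"` input path.
#' @param pool Fixed average-pooling stem factor applied before the first
#'   convolution (default 1, i.e. none); scaled-down configurations can use
#'   2 to run the convolution pyramid on reduced maps. The decoder mirrors
#'   it with a nearest-neighbour upsampling output stage, so input and
#'   reconstruction shapes are unchanged.
#' @param mc_samples Monte-Carlo samples L per input during training
#'   (typically 1).
#' @return An `arch_config` list.
#' @export
arch_config <- function(latent_dim = 64, n_classes = 2, n_subjects = 2,
                        input = c(3, 64, 32),
                        enc_channels = c(32, 64, 128), enc_strides = c(2, 2, 2),
                        enc_dense = 512, ext_channels = c(32, 64),
                        ext_dense = 128, head_dense = c(256, 256, 64),
                        hemi = c("both", "left", "right"), pool = 1,
                        mc_samples = 1) {
  hemi <- match.arg(hemi)
  stopifnot(latent_dim >= 4, latent_dim %% 2 == 0, n_classes >= 2,
            n_subjects >= 1, length(input) == 3, length(enc_channels) == 3,
            length(enc_strides) == 3, length(ext_channels) == 2,
            length(head_dense) == 3, mc_samples >= 1, pool >= 1,
            input[2] %% pool == 0, input[3] %% pool == 0)
  cfg <- structure(
    list(input = as.integer(input), pool = as.integer(pool),
         latent = as.integer(latent_dim),
         enc_channels = as.integer(enc_channels),
         enc_strides = as.integer(enc_strides),
         enc_dense = as.integer(enc_dense),
         ext_channels = as.integer(ext_channels),
         ext_dense = as.integer(ext_dense),
         head_dense = as.integer(head_dense),
         n_classes = as.integer(n_classes), n_subjects = as.integer(n_subjects),
         hemi = hemi, mc_samples = as.integer(mc_samples)),
    class = "arch_config")
  # the dimension chain must be consistent before any parameter is allocated
  sh <- .nn_shapes(cfg)
  stopifnot(sh$emb_dim == cfg$ext_dense, sh$enc_flat > 0)
  cfg
}

#' Initialize model parameters
#'
#' @param arch An [arch_config()].
#' @param seed Integer seed for the weight initialization.
#' @return A named list of parameter matrices (one entry per layer weight,
#'   bias, batch-norm scale/shift and running buffer), class `model_params`.
#' @export
init_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "arch_config"))
  p <- .nn_init(arch, as.integer(seed))
  structure(p, class = "model_params", arch = arch)
}

as_hemi_matrix <- function(x) {
  # accepts 3 x H x W array (single image) or (3*H*W) x N matrix
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) == 3) return(matrix(flatten_hemi(x), ncol = 1))
  stop("expected a 3 x H x W array or a flattened matrix")
}

# flatten band x row x col to the compiled layout r = h + H*(w + W*c)
flatten_hemi <- function(img) {
  as.vector(aperm(img, c(2, 3, 1)))
}

#' Encode a hemisphere image
#'
#' Deterministic inference-mode encoding (batch normalization uses running
#' statistics).
#'
#' @param hemi_image `3 x H x W` array scaled to `[0, 1]`, or a pre-flattened
#'   matrix with one sample per column.
#' @param params [init_model()] parameters.
#' @param side `"left"` or `"right"` (the hemispheric weights are
#'   independent).
#' @return A `latent_code` list with `mu` and `log_var` (length-J vectors, or
#'   J x N matrices for batched input).
#' @export
encode <- function(hemi_image, params, side = c("left", "right")) {
  side <- match.arg(side)
  arch <- attr(params, "arch")
  X <- as_hemi_matrix(hemi_image)
  if (nrow(X) != prod(arch$input)) stop("hemisphere image shape mismatch")
  out <- .nn_encode(params, arch, X, side)
  structure(list(mu = drop(out$mu), log_var = drop(out$log_var)),
            class = "latent_code")
}

#' Reparameterization trick
#'
#' `z = mu + exp(log_var / 2) * eps` with standard-normal `eps`, so sampling
#' is differentiable in the posterior parameters.
#'
#' @param code A `latent_code` (or list with `mu`, `log_var`).
#' @param eps Standard-normal draws matching `mu`; defaults to fresh draws.
#' @return The sampled latent vector `z`.
#' @export
reparameterize <- function(code, eps = NULL) {
  if (is.null(eps)) eps <- stats::rnorm(length(code$mu))
  code$mu + exp(code$log_var / 2) * eps
}

#' Decode a latent code
#'
#' @param z Latent vector (length J) or J x N matrix.
#' @param params [init_model()] parameters.
#' @param side `"left"` or `"right"`.
#' @return Reconstruction in `[0, 1]` as a `3 x H x W` array (or flattened
#'   matrix for batched input).
#' @export
decode <- function(z, params, side = c("left", "right")) {
  side <- match.arg(side)
  arch <- attr(params, "arch")
  Z <- if (is.matrix(z)) z else matrix(z, ncol = 1)
  if (nrow(Z) != arch$latent) stop("latent dimension mismatch")
  Y <- .nn_decode(params, arch, Z, side)
  if (ncol(Y) == 1) unflatten_hemi(Y[, 1], arch$input) else Y
}

unflatten_hemi <- function(v, input) {
  aperm(array(v, c(input[2], input[3], input[1])), c(3, 1, 2))
}

#' Bilateral feature embedding
#'
#' The hemispheric latent codes are stacked as a two-row map and mixed by the
#' 2x2 bilateral convolution stages and dense stages.
#'
#' @param z_left,z_right Latent vectors (length J) or J x N matrices.
#' @param params [init_model()] parameters.
#' @return Embedding vector of length `ext_dense` (or matrix for batches).
#' @export
bilateral_features <- function(z_left, z_right, params) {
  arch <- attr(params, "arch")
  Zl <- if (is.matrix(z_left)) z_left else matrix(z_left, ncol = 1)
  Zr <- if (is.matrix(z_right)) z_right else matrix(z_right, ncol = 1)
  drop(.nn_bilateral(params, arch, Zl, Zr))
}

#' Emotion class probabilities from an embedding
#'
#' @param emb Embedding vector or matrix (one sample per column).
#' @param params [init_model()] parameters.
#' @return Probability vector over emotion classes (columns sum to 1).
#' @export
classify_emotion <- function(emb, params) {
  arch <- attr(params, "arch")
  E <- if (is.matrix(emb)) emb else matrix(emb, ncol = 1)
  drop(.nn_head(params, arch, E, "classifier"))
}

#' Subject probabilities from an embedding
#'
#' The forward pass is an ordinary softmax head; during training its input
#' gradient passes through [grad_reverse()] so the shared layers are pushed
#' toward subject invariance.
#'
#' @param emb Embedding vector or matrix.
#' @param params [init_model()] parameters.
#' @param lambda Reversal strength (forward output does not depend on it).
#' @return Probability vector over subjects.
#' @export
classify_subject <- function(emb, params, lambda = 1) {
  arch <- attr(params, "arch")
  E <- if (is.matrix(emb)) emb else matrix(emb, ncol = 1)
  p <- drop(.nn_head(params, arch, E, "discriminator"))
  attr(p, "lambda") <- lambda
  p
}

#' Gradient reversal layer
#'
#' Identity in the forward direction; during backpropagation the upstream
#' gradient is multiplied by `-lambda`. [grad_reverse()] is the forward pass
#' and [grad_reverse_backward()] the backward contract used by the training
#' steps.
#'
#' @param x Input (returned unchanged).
#' @param lambda Nonnegative reversal scale.
#' @return `x` with the reversal scale attached.
#' @export
grad_reverse <- function(x, lambda = 1) {
  stopifnot(lambda >= 0)
  attr(x, "grl_lambda") <- lambda
  x
}

#' @rdname grad_reverse
#' @param grad Upstream gradient arriving at the layer output.
#' @export
grad_reverse_backward <- function(grad, lambda) {
  -lambda * grad
}

#' Full inference pass
#'
#' Deterministic prediction (z := mu) through the configured hemisphere
#' path, returning class probabilities, subject probabilities, the bilateral
#' embedding and the hemispheric posterior means.
#'
#' @param params [init_model()] parameters.
#' @param x_left,x_right Hemisphere batches: `(3*H*W) x N` matrices in
#'   `[0, 1]` (see [prepare_hemis()]).
#' @return List with `probs`, `subject_probs`, `emb`, `mu_l`, `mu_r`.
#' @export
predict_bivdann <- function(params, x_left, x_right) {
  arch <- attr(params, "arch")
  .nn_predict(params, arch,
              if (is.null(x_left)) matrix(0, 0, 0) else x_left,
              if (is.null(x_right)) matrix(0, 0, 0) else x_right)
}

#' Flatten a topograph dataset into hemisphere design matrices
#'
#' Images are scaled to `[0, 1]` and split at the vertical midline.
#'
#' @param ds A `topograph_dataset`.
#' @return List with `x_left`, `x_right` (`(3*H*(W/2)) x N` matrices),
#'   integer `y` (0-based class codes), `s` (0-based subject codes), and the
#'   factor levels `classes`, `subjects`.
#' @export
prepare_hemis <- function(ds) {
  stopifnot(inherits(ds, "topograph_dataset"))
  d <- dim(ds$images)
  n <- d[1]; half <- d[4] %/% 2
  # layout per column: row fastest, then column, then band (matches the
  # compiled feature-map order)
  xl <- matrix(aperm(ds$images[, , , seq_len(half), drop = FALSE],
                     c(3, 4, 2, 1)) / 255, ncol = n)
  xr <- matrix(aperm(ds$images[, , , (half + 1):d[4], drop = FALSE],
                     c(3, 4, 2, 1)) / 255, ncol = n)
  classes <- sort(unique(ds$meta$label))
  subjects <- sort(unique(ds$meta$subject_id))
  list(x_left = xl, x_right = xr,
       y = match(ds$meta$label, classes) - 1L,
       s = match(ds$meta$subject_id, subjects) - 1L,
       classes = classes, subjects = subjects)
}
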