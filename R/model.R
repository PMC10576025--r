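# The interpretable splicing model: four strength-computation modules
# (SCMs), a learnable basal strength B, and a learned scalar-to-PSI link
# (affine-sigmoid "prime" tuner, or a small residual MLP "full" tuner).
#
# model(x) = Tuner( f_incl_seq + f_incl_struct - f_skip_seq - f_skip_struct + B )
#
# Each SCM is: valid-mode cross-correlation over one-hot channels ->
# per-position learned bias -> softplus -> sum. Sequence SCMs see 4
# channels (A,C,G,U); structure SCMs see 8 (sequence, dot-bracket
# categories "(", ".", ")", and the G-U wobble indicator).

SCM_NAMES <- c("incl_seq", "incl_struct", "skip_seq", "skip_struct")

#' One-hot encode a model input triple
#'
#' @param sequence RNA (or DNA) string of length `d`.
#' @param structure Dot-bracket string of length `d`.
#' @param wobble Optional 0/1 vector or string of length `d`; computed
#'   from `sequence`/`structure` via [wobble_vector()] when `NULL`.
#' @return An `encoded_input`: list with `x_seq` (d x 4, channel order
#'   A,C,G,U), `x_struct` (d x 3, order "(", ".", ")"), `x_wobble`
#'   (d x 1), and `d`.
#' @export
encode_input <- function(sequence, structure, wobble = NULL) {
  sequence <- rna_normalize(sequence)
  d <- nchar(sequence)
  if (nchar(structure) != d) abort("sequence and structure lengths differ")
  if (is.null(wobble)) wobble <- wobble_vector(sequence, structure)
  if (is.character(wobble)) wobble <- as.integer(strsplit(wobble, "")[[1]])
  if (length(wobble) != d) abort("wobble length differs from sequence length")
  s <- strsplit(sequence, "")[[1]]
  st <- strsplit(structure, "")[[1]]
  if (!all(st %in% STRUCT_LEVELS)) abort("invalid structure character")
  x_seq <- matrix(0, d, 4, dimnames = list(NULL, SEQ_LEVELS))
  x_seq[cbind(seq_len(d), match(s, SEQ_LEVELS))] <- 1
  x_struct <- matrix(0, d, 3, dimnames = list(NULL, STRUCT_LEVELS))
  x_struct[cbind(seq_len(d), match(st, STRUCT_LEVELS))] <- 1
  structure(list(x_seq = x_seq, x_struct = x_struct,
                 x_wobble = matrix(as.numeric(wobble), d, 1), d = d),
            class = "encoded_input")
}

#' Decode an encoded input back to strings
#'
#' @param encoded An [encode_input()] result.
#' @return List with `sequence`, `structure`, `wobble`.
#' @export
decode_input <- function(encoded) {
  list(sequence = paste(SEQ_LEVELS[max.col(encoded$x_seq)], collapse = ""),
       structure = paste(STRUCT_LEVELS[max.col(encoded$x_struct)], collapse = ""),
       wobble = paste(as.integer(encoded$x_wobble[, 1]), collapse = ""))
}

#' Valid-mode 1D cross-correlation of channels with a filter bank
#'
#' `z[p, f] = sum_{i, ch} x[p + i - 1, ch] * alpha[i, ch, f]` — the raw
#' strengths before position bias and activation. No padding, no kernel
#' flip.
#'
#' @param x Numeric matrix `d x c`.
#' @param alpha Numeric array `w x c x k`.
#' @return Numeric matrix `(d - w + 1) x k`.
#' @export
scm_convolve <- function(x, alpha) {
  d <- nrow(x); w <- dim(alpha)[1]; c <- dim(alpha)[2]; k <- dim(alpha)[3]
  if (ncol(x) != c) abort("channel count of x does not match kernel")
  if (w > d) abort("filter width exceeds input length")
  P <- d - w + 1L
  z <- matrix(0, P, k)
  for (f in seq_len(k)) {
    af <- alpha[, , f, drop = FALSE]
    dim(af) <- c(w, c)
    for (p in seq_len(P)) {
      z[p, f] <- sum(x[p:(p + w - 1L), , drop = FALSE] * af)
    }
  }
  z
}

#' Forward pass of one strength-computation module
#'
#' Convolution, position bias, softplus, sum. The full strength map is
#' retained for interpretation.
#'
#' @param x Numeric input matrix `d x c` (see [encode_input()]; structure
#'   SCMs take `cbind(x_seq, x_struct, x_wobble)`).
#' @param params List with `alpha` (`w x c x k`) and `beta`
#'   (`(d - w + 1) x k`).
#' @return List with `strengths` (post-softplus map), `pre` (position-
#'   adjusted raw strengths `z + beta`), and `total`.
#' @export
scm_forward <- function(x, params) {
  z <- scm_convolve(x, params$alpha)
  if (!all(dim(z) == dim(params$beta))) {
    abort("position-bias shape inconsistent with convolution output")
  }
  pre <- z + params$beta
  strengths <- softplus(pre)
  list(strengths = strengths, pre = pre, total = sum(strengths))
}

#' Affine-sigmoid link (early-stage tuner)
#'
#' @param delta Delta strength.
#' @param nu Slope.
#' @param eta Offset.
#' @return `sigmoid(nu * delta + eta)`.
#' @export
tuner_prime <- function(delta, nu, eta) {
  sigmoid(nu * delta + eta)
}

#' Residual MLP link (final tuner)
#'
#' A 3-layer fully connected network on the scalar delta strength with a
#' residual connection from the input to the output layer, followed by a
#' sigmoid.
#'
#' @param delta Delta strength (vectorized).
#' @param tuner Tuner parameter list (`W1`, `b1`, `W2`, `b2`, `w3`, `b3`,
#'   residual weight `r`), as stored in a `splice_model`.
#' @return Predicted PSI in `(0, 1)`.
#' @export
tuner_full <- function(delta, tuner) {
  vapply(delta, function(x) {
    h1 <- tanh(tuner$W1 * x + tuner$b1)
    h2 <- tanh(as.vector(tuner$W2 %*% h1) + tuner$b2)
    sigmoid(sum(tuner$w3 * h2) + tuner$b3 + tuner$r * x)
  }, numeric(1))
}

init_scm <- function(w, c, k, d, init_sd = 0.05, beta_init = -4) {
  P <- d - w + 1L
  list(alpha = array(rnorm(w * c * k, sd = init_sd), dim = c(w, c, k)),
       beta = matrix(beta_init, P, k))
}

new_tuner_prime <- function(nu = 1, eta = 0) {
  list(type = "prime", nu = nu, eta = eta)
}

new_tuner_full <- function(nu = 1, eta = 0, hidden = 10, init_sd = 0.1) {
  # W3 starts at zero so the freshly promoted tuner reproduces the
  # affine-sigmoid exactly; hidden units get small random pre-activations
  # so gradients can flow once training resumes
  list(type = "full",
       W1 = rnorm(hidden, sd = init_sd), b1 = rnorm(hidden, sd = init_sd),
       W2 = matrix(rnorm(hidden * hidden, sd = init_sd), hidden, hidden),
       b2 = rnorm(hidden, sd = init_sd),
       w3 = rep(0, hidden), b3 = eta, r = nu)
}

#' Construct an untrained splicing balance model
#'
#' @param d Input window length (default 90).
#' @param n_filters_seq Filters per sequence SCM (default 20, width 6).
#' @param n_filters_struct Filters per structure SCM (default 8, width 30).
#' @param tuner `"prime"` (affine sigmoid) or `"full"` (residual MLP).
#' @param tuner_hidden Hidden width of the full tuner.
#' @param init_sd Kernel initialization s.d.
#' @param beta_init Initial position bias (negative keeps initial
#'   strengths small).
#' @param seed Optional seed for the random initialization.
#' @return An object of class `splice_model`.
#' @export
splice_model <- function(d = 90, n_filters_seq = 20, n_filters_struct = 8,
                         tuner = c("prime", "full"), tuner_hidden = 10,
                         init_sd = 0.05, beta_init = -4, seed = NULL) {
  tuner <- match.arg(tuner)
  d <- as.integer(d)
  if (d < 30) abort("window length d must be >= 30 (the structure filter width)")
  if (!is.null(seed)) set.seed(seed)
  scms <- list(
    incl_seq = init_scm(6L, 4L, n_filters_seq, d, init_sd, beta_init),
    incl_struct = init_scm(30L, 8L, n_filters_struct, d, init_sd, beta_init),
    skip_seq = init_scm(6L, 4L, n_filters_seq, d, init_sd, beta_init),
    skip_struct = init_scm(30L, 8L, n_filters_struct, d, init_sd, beta_init))
  tun <- if (tuner == "prime") new_tuner_prime() else new_tuner_full(hidden = tuner_hidden)
  structure(list(scms = scms, B = 0, tuner = tun, d = d,
                 use_struct = TRUE, stage = 0L, history = NULL,
                 channels = list(seq = SEQ_LEVELS, struct = STRUCT_LEVELS,
                                 struct_input = c(SEQ_LEVELS, STRUCT_LEVELS, "wobble"))),
            class = "splice_model")
}

#' @export
print.splice_model <- function(x, ...) {
  ks <- dim(x$scms$incl_seq$alpha)[3]
  kt <- dim(x$scms$incl_struct$alpha)[3]
  cat(sprintf("<splice_model> d = %d | %d sequence filters (w=6) + %d structure filters (w=30) per side\n",
              x$d, ks, kt))
  cat(sprintf("  tuner: %s | basal B = %.4f | trained through stage %d%s\n",
              x$tuner$type, x$B, x$stage,
              if (x$use_struct) "" else " (sequence SCMs only)"))
  invisible(x)
}

#' Reference forward pass on one encoded input
#'
#' Computes the four SCM totals, the delta strength (inclusion minus
#' skipping plus basal B) and the tuner output, exposing every
#' per-position, per-filter strength for interpretation. This is the
#' plain-R reference path; [predict.splice_model()] uses the equivalent
#' compiled path.
#'
#' @param encoded An [encode_input()] object.
#' @param model A `splice_model`.
#' @return List with `psi_hat`, `delta`, `totals` (named), and
#'   `strength_maps` (per-SCM list from [scm_forward()]).
#' @export
model_forward <- function(encoded, model) {
  if (encoded$d != model$d) abort("input length does not match model d")
  x_struct_in <- cbind(encoded$x_seq, encoded$x_struct, encoded$x_wobble)
  active <- if (model$use_struct) SCM_NAMES else c("incl_seq", "skip_seq")
  maps <- list()
  totals <- c(incl_seq = 0, incl_struct = 0, skip_seq = 0, skip_struct = 0)
  for (nm in active) {
    x <- if (grepl("struct", nm)) x_struct_in else encoded$x_seq
    maps[[nm]] <- scm_forward(x, model$scms[[nm]])
    totals[nm] <- maps[[nm]]$total
  }
  delta <- totals[["incl_seq"]] + totals[["incl_struct"]] -
    totals[["skip_seq"]] - totals[["skip_struct"]] + model$B
  psi_hat <- if (model$tuner$type == "prime") {
    tuner_prime(delta, model$tuner$nu, model$tuner$eta)
  } else {
    tuner_full(delta, model$tuner)
  }
  list(psi_hat = psi_hat, delta = delta, totals = totals, strength_maps = maps)
}

encode_dataset <- function(data, d = NULL) {
  data <- as_tibble(data)
  stopifnot(all(c("sequence", "structure", "wobble") %in% names(data)))
  seqm <- seq_to_int(rna_normalize(data$sequence))
  structm <- struct_to_int(data$structure)
  wobm <- wobble_to_int(data$wobble)
  if (!is.null(d) && ncol(seqm) != d) {
    abort(sprintf("dataset window length %d does not match model d = %d",
                  ncol(seqm), d))
  }
  list(seqm = seqm, structm = structm, wobm = wobm)
}

#' Predict PSI for a dataset
#'
#' @param object A `splice_model`.
#' @param newdata Tibble with `sequence`, `structure`, `wobble` columns.
#' @param ... Unused.
#' @return The input tibble with added columns `.delta`, `.psi_hat`, and
#'   the four per-side SCM totals (`.f_incl_seq`, `.f_incl_struct`,
#'   `.f_skip_seq`, `.f_skip_struct`).
#' @export
predict.splice_model <- function(object, newdata, ...) {
  enc <- encode_dataset(newdata, d = object$d)
  out <- cpp_model_eval(enc$seqm, enc$structm, enc$wobm, object$scms,
                        object$B, object$tuner, object$use_struct)
  newdata <- as_tibble(newdata)
  newdata$.f_incl_seq <- out$totals[, 1]
  newdata$.f_incl_struct <- out$totals[, 2]
  newdata$.f_skip_seq <- out$totals[, 3]
  newdata$.f_skip_struct <- out$totals[, 4]
  newdata$.delta <- out$delta
  newdata$.psi_hat <- out$psi
  newdata
}
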