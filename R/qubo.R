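#' Build the binary QUBO for least-squares reconstruction
#'
#' Maps the least-squares objective `||M x - y||^2` over binary pixel values
#' to a quadratic unconstrained binary optimization model. Because
#' `x_i^2 = x_i` for binary variables, the diagonal of `M'M` folds into the
#' linear bias:
#' `linear_i = (M'M)_ii - 2 (M'y)_i`, `coupler_ij = 2 (M'M)_ij` for `i < j`,
#' and the constant offset `y'y` is kept inside the model so every reported
#' energy is directly a squared residual. Couplers with magnitude below
#' 1e-12 are dropped (the system matrix is sparse; exact zeros stay out of
#' the model graph).
#'
#' @param M a `system_matrix` or plain `m x n` matrix.
#' @param y measurement vector (length m), or a [sinogram] (vectorized
#'   row-major).
#' @return a `qubo_model`: list with `n_vars`, `linear`, `couplers`
#'   (three-column matrix `i, j, value` with `i < j`), `offset`.
#' @export
build_binary_qubo <- function(M, y) {
  m <- system_values(M)
  y <- as_measurement_vector(y)
  if (length(y) != nrow(m)) {
    stop("dimension mismatch between system matrix and measurement vector",
         call. = FALSE)
  }
  mtm <- crossprod(m)
  mty <- as.numeric(crossprod(m, y))
  linear <- diag(mtm) - 2 * mty
  couplers <- upper_couplers(2 * mtm)
  new_qubo_model(ncol(m), linear, couplers, offset = sum(y^2))
}

as_measurement_vector <- function(y) {
  if (inherits(y, "sinogram")) vec_sinogram(y) else as.numeric(y)
}

new_qubo_model <- function(n_vars, linear, couplers, offset) {
  structure(list(n_vars = as.integer(n_vars),
                 linear = as.numeric(linear),
                 couplers = couplers,
                 offset = as.numeric(offset)),
            class = "qubo_model")
}

empty_couplers <- function() {
  matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("i", "j", "value")))
}

# extract strict upper triangle of a symmetric coefficient matrix as
# (i, j, value) rows, dropping magnitudes below 1e-12
upper_couplers <- function(q) {
  idx <- which(upper.tri(q) & abs(q) > 1e-12, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_couplers())
  out <- cbind(i = idx[, 1], j = idx[, 2], value = q[idx])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' @export
print.qubo_model <- function(x, ...) {
  cat(sprintf("<qubo_model %d variables, %d couplers, offset %.6g>\n",
              x$n_vars, nrow(x$couplers), x$offset))
  invisible(x)
}

#' Evaluate a model's energy at an assignment
#'
#' Returns the full objective value including the constant offset, so for
#' models built from `(M, y)` the energy of any feasible assignment equals
#' the squared residual `||M x - y||^2`.
#'
#' @param model a `qubo_model`, `integer_model`, or `ising_model`.
#' @param x assignment vector in the model's domain (binary 0/1, bounded
#'   integer, or spins -1/+1 respectively).
#' @return scalar energy.
#' @export
model_energy <- function(model, x) UseMethod("model_energy")

#' @export
model_energy.qubo_model <- function(model, x) {
  x <- as.numeric(x)
  if (length(x) != model$n_vars) stop("assignment length mismatch", call. = FALSE)
  if (!all(x %in% c(0, 1))) stop("QUBO assignment must be binary 0/1", call. = FALSE)
  e <- sum(model$linear * x) + model$offset
  if (nrow(model$couplers) > 0L) {
    e <- e + sum(model$couplers[, "value"] *
                   x[model$couplers[, "i"]] * x[model$couplers[, "j"]])
  }
  e
}

#' @export
model_energy.integer_model <- function(model, x) {
  x <- as.numeric(x)
  if (length(x) != model$n_vars) stop("assignment length mismatch", call. = FALSE)
  if (any(x != round(x)) || any(x < 0) || any(x > model$upper_bound)) {
    stop("assignment outside the model's integer domain", call. = FALSE)
  }
  e <- sum(model$linear * x) + sum(model$quad_diag * x^2) + model$constant
  if (nrow(model$quad) > 0L) {
    e <- e + sum(model$quad[, "value"] *
                   x[model$quad[, "i"]] * x[model$quad[, "j"]])
  }
  e
}

#' @export
model_energy.ising_model <- function(model, x) {
  x <- as.numeric(x)
  if (length(x) != model$n_vars) stop("assignment length mismatch", call. = FALSE)
  if (!all(x %in% c(-1, 1))) stop("Ising assignment must be spins -1/+1", call. = FALSE)
  e <- sum(model$h * x) + model$offset
  if (nrow(model$J) > 0L) {
    e <- e + sum(model$J[, "value"] * x[model$J[, "i"]] * x[model$J[, "j"]])
  }
  e
}

# batch energies for a 0/1 assignment matrix (rows = assignments)
qubo_energies <- function(model, X) {
  q <- matrix(0, model$n_vars, model$n_vars)
  diag(q) <- model$linear
  if (nrow(model$couplers) > 0L) {
    ij <- model$couplers
    q[ij[, 1:2, drop = FALSE]] <- q[ij[, 1:2, drop = FALSE]] + ij[, 3] / 2
    q[ij[, 2:1, drop = FALSE]] <- q[ij[, 2:1, drop = FALSE]] + ij[, 3] / 2
  }
  rowSums((X %*% q) * X) + model$offset
}

#' Convert a QUBO to its Ising equivalent
#'
#' Applies the exact substitution `x = (s + 1) / 2`, so the Ising energy of
#' every spin assignment equals the QUBO energy of the corresponding binary
#' assignment, offsets included.
#'
#' @param model a `qubo_model`.
#' @return an `ising_model`: list with `n_vars`, `h`, `J` (matrix
#'   `i, j, value`, `i < j`), `offset`.
#' @export
qubo_to_ising <- function(model) {
  h <- model$linear / 2
  offset <- model$offset + sum(model$linear) / 2
  J <- empty_couplers()
  if (nrow(model$couplers) > 0L) {
    v <- model$couplers[, "value"]
    J <- cbind(i = model$couplers[, "i"], j = model$couplers[, "j"],
               value = v / 4)
    # cross terms x_i x_j = (s_i s_j + s_i + s_j + 1) / 4
    for (k in seq_along(v)) {
      h[model$couplers[k, "i"]] <- h[model$couplers[k, "i"]] + v[k] / 4
      h[model$couplers[k, "j"]] <- h[model$couplers[k, "j"]] + v[k] / 4
    }
    offset <- offset + sum(v) / 4
  }
  structure(list(n_vars = model$n_vars, h = h, J = J, offset = offset),
            class = "ising_model")
}

#' @export
print.ising_model <- function(x, ...) {
  cat(sprintf("<ising_model %d spins, %d couplings, offset %.6g>\n",
              x$n_vars, nrow(x$J), x$offset))
  invisible(x)
}

#' Build the bounded-integer quadratic model
#'
#' Expresses `||M x - y||^2` over integer pixel values `x_i` in
#' `[0, upper_bound]`. Unlike the binary case, `x_i^2 != x_i`, so the
#' squared-term coefficients `(M'M)_ii` are stored explicitly (`quad_diag`)
#' rather than folded into the linear part; off-diagonal pairs are stored
#' once with the doubled coefficient.
#'
#' @inheritParams build_binary_qubo
#' @param upper_bound largest allowed pixel value (>= 1), e.g.
#'   `levels - 1`.
#' @return an `integer_model`.
#' @export
build_integer_model <- function(M, y, upper_bound) {
  m <- system_values(M)
  y <- as_measurement_vector(y)
  upper_bound <- as.integer(upper_bound)
  if (upper_bound < 1L) stop("upper_bound must be >= 1", call. = FALSE)
  if (length(y) != nrow(m)) {
    stop("dimension mismatch between system matrix and measurement vector",
         call. = FALSE)
  }
  mtm <- crossprod(m)
  structure(list(n_vars = ncol(m),
                 linear = as.numeric(-2 * crossprod(m, y)),
                 quad_diag = diag(mtm),
                 quad = upper_couplers(2 * mtm),
                 constant = sum(y^2),
                 upper_bound = upper_bound),
            class = "integer_model")
}

#' @export
print.integer_model <- function(x, ...) {
  cat(sprintf("<integer_model %d variables in [0, %d], %d pairs>\n",
              x$n_vars, x$upper_bound, nrow(x$quad)))
  invisible(x)
}

#' Encode a bounded-integer model as a binary QUBO
#'
#' Standard positional binary encoding: pixel `p` becomes `bits` binary
#' variables with weights `2^0 ... 2^(bits-1)` (variable index
#' `(p - 1) * bits + b`), giving `n_vars * bits` fully coupled binary
#' variables in total. The QUBO energy of the bit image of any in-range
#' integer assignment equals the integer model's objective exactly.
#'
#' @param model an `integer_model`.
#' @param bits bits per pixel R; the representable cap `2^bits - 1` must be
#'   at least the model's `upper_bound`.
#' @return list with elements `qubo` (a `qubo_model`) and `encoding` (a
#'   `binary_encoding` with `n_pixels`, `bits`, `weights`).
#' @export
encode_integer_as_binary <- function(model, bits) {
  bits <- as.integer(bits)
  if (bits < 1L) stop("bits must be >= 1", call. = FALSE)
  cap <- 2^bits - 1
  if (cap < model$upper_bound) {
    stop(sprintf("%d bit(s) represent at most %d < upper_bound %d",
                 bits, cap, model$upper_bound), call. = FALSE)
  }
  p_n <- model$n_vars
  w <- 2^(0:(bits - 1L))
  n_bin <- p_n * bits
  var_of <- function(p, b) (p - 1L) * bits + b

  linear <- numeric(n_bin)
  coup <- new.env(parent = emptyenv())
  add_coupler <- function(i, j, v) {
    key <- paste0(i, "_", j)
    old <- coup[[key]]
    coup[[key]] <- if (is.null(old)) c(i, j, v) else old + c(0, 0, v)
  }
  for (p in seq_len(p_n)) {
    for (b in seq_len(bits)) {
      # a_p x_p -> a_p w_b z ; d_p x_p^2 -> d_p w_b^2 z (z^2 = z) + cross bits
      linear[var_of(p, b)] <- model$linear[p] * w[b] +
        model$quad_diag[p] * w[b]^2
    }
    if (bits > 1L && model$quad_diag[p] != 0) {
      for (b1 in 1:(bits - 1L)) for (b2 in (b1 + 1L):bits) {
        add_coupler(var_of(p, b1), var_of(p, b2),
                    2 * model$quad_diag[p] * w[b1] * w[b2])
      }
    }
  }
  if (nrow(model$quad) > 0L) {
    for (k in seq_len(nrow(model$quad))) {
      p <- model$quad[k, "i"]; q <- model$quad[k, "j"]
      v <- model$quad[k, "value"]
      for (b1 in seq_len(bits)) for (b2 in seq_len(bits)) {
        add_coupler(var_of(p, b1), var_of(q, b2), v * w[b1] * w[b2])
      }
    }
  }
  keys <- ls(coup)
  couplers <- if (length(keys) == 0L) empty_couplers() else {
    rows <- t(vapply(keys, function(k) coup[[k]], numeric(3)))
    dimnames(rows) <- list(NULL, c("i", "j", "value"))
    rows <- rows[abs(rows[, "value"]) > 1e-12, , drop = FALSE]
    rows[order(rows[, "i"], rows[, "j"]), , drop = FALSE]
  }
  qubo <- new_qubo_model(n_bin, linear, couplers, offset = model$constant)
  encoding <- structure(list(n_pixels = p_n, bits = bits, weights = w),
                        class = "binary_encoding")
  list(qubo = qubo, encoding = encoding)
}

#' Decode bit assignments back to integer pixel values
#'
#' @param x binary assignment vector of length `n_pixels * bits` (pixel
#'   bits contiguous, least-significant first).
#' @param encoding a `binary_encoding` from [encode_integer_as_binary()].
#' @return integer vector of pixel values.
#' @export
decode_binary <- function(x, encoding) {
  if (is.null(encoding)) return(as.numeric(x))
  if (length(x) != encoding$n_pixels * encoding$bits) {
    stop("bit vector length does not match the encoding", call. = FALSE)
  }
  as.numeric(encoding$weights %*% matrix(x, nrow = encoding$bits))
}

#' Serialize models to and from JSON
#'
#' Round-trips are lossless at double precision. The layout is
#' `{n_vars, linear, couplers: [[i, j, value], ...], offset}`.
#'
#' @param model a `qubo_model`.
#' @param path file path.
#' @name qubo_json
#' @export
write_qubo_json <- function(model, path) {
  couplers <- lapply(seq_len(nrow(model$couplers)), function(k) {
    as.numeric(model$couplers[k, ])
  })
  jsonlite::write_json(
    list(n_vars = model$n_vars, linear = model$linear,
         couplers = couplers, offset = model$offset),
    path, auto_unbox = TRUE, digits = I(17))  # 17 significant digits round-trip doubles
  invisible(path)
}

#' @rdname qubo_json
#' @export
read_qubo_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  couplers <- if (length(obj$couplers) == 0L) empty_couplers() else {
    m <- if (is.matrix(obj$couplers)) obj$couplers else
      do.call(rbind, obj$couplers)
    dimnames(m) <- list(NULL, c("i", "j", "value"))
    m
  }
  new_qubo_model(obj$n_vars, obj$linear, couplers, obj$offset)
}
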