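# internal helpers shared across modules

# Deterministic substream seed derived from a master seed and stream indices.
# Kept strictly below 2^31 so it is always a valid set.seed() argument.
derive_seed <- function(seed, ...) {
  m <- 2147483629
  s <- as.double(seed) %% m
  for (k in as.double(c(...))) {
    s <- (s * 69069 + k * 10007 + 1) %% m
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("%s must be finite (got non-finite values)", what),
         call. = FALSE)
  }
  invisible(x)
}

check_binary <- function(z, what = "treatment") {
  if (anyNA(z) || !all(z %in% c(0, 1))) {
    stop(sprintf("%s must be coded 0/1 with no missing values", what),
         call. = FALSE)
  }
  invisible(as.numeric(z))
}

as_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  x
}

# row-resample a data.frame, matrix, or list of equal-length row structures
resample_rows <- function(data, idx) {
  if (is.data.frame(data) || is.matrix(data)) {
    return(data[idx, , drop = FALSE])
  }
  if (is.list(data)) {
    return(lapply(data, resample_rows, idx = idx))
  }
  data[idx]
}

n_rows <- function(data) {
  if (is.data.frame(data) || is.matrix(data)) return(nrow(data))
  if (is.list(data)) return(n_rows(data[[1]]))
  length(data)
}
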