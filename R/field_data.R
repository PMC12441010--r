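#' Construct a field dataset with declared variable roles
#'
#' Wraps a data frame shaped like a park-clustered wildlife survey:
#' one binary park-level treatment (artificial feeding), escape-behavior
#' outcomes (flight initiation distance FID, vertical escape distance VED),
#' four confounders that drive both feeding and behavior, and six further
#' covariates that predict behavior only. Missing values are allowed in
#' every numeric column; the treatment must be fully observed and coded
#' 0/1, and must be constant within a park.
#'
#' @param data data frame holding all declared columns.
#' @param outcomes,treatment,confounders,covariates,park character names of
#'   the role columns. `park` may be `NULL` when no cluster id exists.
#' @return An object of class `field_dataset`: list with `data` and `roles`.
#' @seealso [generate_field_like()], [read_field_csv()]
#' @export
field_dataset <- function(data,
                          outcomes = c("FID", "VED"),
                          treatment = "Feeding",
                          confounders = c("NH", "TN", "PGS", "P"),
                          covariates = c("TD", "DT", "CO", "PL", "NP", "RG"),
                          park = "park_id") {
  stopifnot(is.data.frame(data))
  roles <- list(outcomes = outcomes, treatment = treatment,
                confounders = confounders, covariates = covariates,
                park = park)
  declared <- c(outcomes, treatment, confounders, covariates, park)
  missing_cols <- setdiff(declared, names(data))
  if (length(missing_cols)) {
    stop("missing role columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(intersect(confounders, covariates))) {
    stop("confounder and covariate roles must be disjoint", call. = FALSE)
  }
  if (treatment %in% c(confounders, covariates, outcomes)) {
    stop("treatment cannot also be a confounder, covariate, or outcome",
         call. = FALSE)
  }
  check_binary(data[[treatment]], sprintf("treatment column '%s'", treatment))
  if (!is.null(park)) {
    per_park <- tapply(data[[treatment]], data[[park]],
                       function(v) length(unique(v)))
    if (any(per_park > 1L)) {
      stop("treatment must be constant within each park", call. = FALSE)
    }
  }
  structure(list(data = data, roles = roles), class = "field_dataset")
}

numeric_role_columns <- function(fd) {
  c(fd$roles$outcomes, fd$roles$confounders, fd$roles$covariates)
}

#' Missingness mask of a field dataset
#'
#' @param fd a [field_dataset()].
#' @return Logical matrix over the numeric role columns; `TRUE` marks a
#'   missing cell.
#' @export
missing_mask <- function(fd) {
  stopifnot(inherits(fd, "field_dataset"))
  is.na(as.matrix(fd$data[, numeric_role_columns(fd), drop = FALSE]))
}

#' @export
print.field_dataset <- function(x, ...) {
  cat("<field_dataset>", nrow(x$data), "observations")
  if (!is.null(x$roles$park)) {
    cat(" in", length(unique(x$data[[x$roles$park]])), "parks")
  }
  cat("\n  treatment:", x$roles$treatment,
      sprintf("(%d treated rows)", sum(x$data[[x$roles$treatment]])), "\n")
  cat("  outcomes:   ", paste(x$roles$outcomes, collapse = ", "), "\n")
  cat("  confounders:", paste(x$roles$confounders, collapse = ", "), "\n")
  cat("  covariates: ", paste(x$roles$covariates, collapse = ", "), "\n")
  nmiss <- sum(missing_mask(x))
  cat("  missing cells:", nmiss, "\n")
  invisible(x)
}

#' Generate synthetic field data shaped like the squirrel case study
#'
#' Emulates the structure of a park-clustered escape-behavior survey:
#' park-level confounders (NH, TN, PGS, P) drawn standard normal; a
#' park-level feeding indicator drawn Bernoulli with logistic probability
#' in the confounders; observation-level covariates (TD, DT, CO, PL, NP,
#' RG) standard normal; outcomes FID and VED generated linearly with the
#' stated treatment effects plus unit normal noise; and missing cells
#' punched completely at random into the numeric columns (never into the
#' treatment or the park id).
#'
#' @param n_parks number of park clusters (at least 2).
#' @param obs_per_park observations per park.
#' @param feed_coefs length-4 confounder coefficients in the feeding model.
#' @param outcome_coefs named list mapping role to a single coefficient
#'   applied to every column of that role: `confounder` and `covariate`.
#' @param effect_fid,effect_ved treatment effects on the two outcomes.
#' @param missing_rate MCAR missingness probability per numeric cell,
#'   in `[0, 1)`.
#' @param seed optional integer seed.
#' @param max_retry resample cap for degenerate all-treated/all-control
#'   feeding draws (the propensity model needs both classes).
#' @return A [field_dataset()].
#' @examples
#' fd <- generate_field_like(n_parks = 12, obs_per_park = 10, seed = 1)
#' fd
#' @export
generate_field_like <- function(n_parks = 12, obs_per_park = 10,
                                feed_coefs = c(0.8, 0.8, 0.8, 0.8),
                                outcome_coefs = list(confounder = 0.5,
                                                     covariate = 0.3),
                                effect_fid = -1.0, effect_ved = -1.0,
                                missing_rate = 0.05, seed = NULL,
                                max_retry = 100) {
  if (n_parks < 2) stop("n_parks must be at least 2", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (length(feed_coefs) != 4L) {
    stop("feed_coefs must have length 4", call. = FALSE)
  }
  conf_names <- c("NH", "TN", "PGS", "P")
  cov_names <- c("TD", "DT", "CO", "PL", "NP", "RG")
  with_seed(seed, {
    feeding <- NULL
    for (attempt in seq_len(max_retry)) {
      conf <- matrix(rnorm(n_parks * 4L), n_parks, 4L,
                     dimnames = list(NULL, conf_names))
      p_feed <- plogis(drop(conf %*% feed_coefs))
      feeding <- rbinom(n_parks, 1L, p_feed)
      if (length(unique(feeding)) == 2L) break
      feeding <- NULL
    }
    if (is.null(feeding)) {
      stop("could not draw a feeding assignment with both classes after ",
           max_retry, " attempts", call. = FALSE)
    }
    n <- n_parks * obs_per_park
    park_id <- rep(seq_len(n_parks), each = obs_per_park)
    covs <- matrix(rnorm(n * 6L), n, 6L, dimnames = list(NULL, cov_names))
    conf_rows <- conf[park_id, , drop = FALSE]
    feed_rows <- feeding[park_id]
    lin <- drop(conf_rows %*% rep(outcome_coefs$confounder, 4L)) +
      drop(covs %*% rep(outcome_coefs$covariate, 6L))
    fid <- effect_fid * feed_rows + lin + rnorm(n)
    ved <- effect_ved * feed_rows + lin + rnorm(n)
    df <- data.frame(park_id = park_id, FID = fid, VED = ved,
                     Feeding = feed_rows)
    df <- cbind(df, as.data.frame(conf_rows), as.data.frame(covs))
    if (missing_rate > 0) {
      num_cols <- c("FID", "VED", conf_names, cov_names)
      for (cn in num_cols) {
        holes <- runif(n) < missing_rate
        df[[cn]][holes] <- NA_real_
      }
    }
    field_dataset(df)
  })
}

#' Read a field dataset from a CSV file with a role map
#'
#' The CSV must have a header row; empty cells and the literal string
#' `"NA"` are read as missing. Roles may be given as a list (see
#' [field_dataset()] arguments) or as the path to a JSON file holding the
#' same fields.
#'
#' @param path CSV file path.
#' @param roles named list of role columns, or path to a JSON role map
#'   with fields `outcomes`, `treatment`, `confounders`, `covariates`,
#'   and optionally `park`.
#' @return A [field_dataset()].
#' @export
read_field_csv <- function(path, roles = NULL) {
  df <- read.csv(path, na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (is.character(roles) && length(roles) == 1L) {
    roles <- jsonlite::read_json(roles, simplifyVector = TRUE)
  }
  args <- list(data = df)
  if (!is.null(roles)) {
    keep <- intersect(names(roles),
                      c("outcomes", "treatment", "confounders",
                        "covariates", "park"))
    args <- c(args, roles[keep])
  }
  tr <- if (!is.null(roles$treatment)) roles$treatment else "Feeding"
  if (tr %in% names(df) && !all(df[[tr]] %in% c(0, 1)) ) {
    stop(sprintf("treatment column '%s' must be coded 0/1", tr),
         call. = FALSE)
  }
  do.call(field_dataset, args)
}

#' Write a field dataset to CSV (plus an optional JSON role map)
#'
#' Missing cells are written as `"NA"`. When `roles_path` is given the
#' role assignment travels with the data as a JSON sidecar, so the pair
#' round-trips through [read_field_csv()].
#'
#' @param fd a [field_dataset()].
#' @param path output CSV path.
#' @param roles_path optional JSON path for the role map.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(fd, path, roles_path = NULL) {
  stopifnot(inherits(fd, "field_dataset"))
  write.csv(fd$data, path, row.names = FALSE, na = "NA")
  if (!is.null(roles_path)) {
    jsonlite::write_json(fd$roles, roles_path, auto_unbox = FALSE,
                         null = "null")
  }
  invisible(path)
}
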