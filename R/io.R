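#' Read and write minute-epoch CSV files
#'
#' One row per minute: `participant_id`, `day_index`, `minute_index`,
#' `counts`, `posture`. The same schema is accepted for real device exports.
#'
#' @param epochs Minute-epoch data frame.
#' @param path File path.
#' @return `read_epochs` returns the data frame; `write_epochs` returns
#'   `path` invisibly.
#' @export
write_epochs <- function(epochs, path) {
  utils::write.csv(epochs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character",
                                 posture = "character"))
}

#' Read and write Ct matrices with assay annotation
#'
#' Wide CSV: columns `assay`, `role`, then one column per sample/pool.
#'
#' @param ct Numeric Ct matrix (rows = assays).
#' @param assays Assay annotation data frame (`assay`, `role`).
#' @param path File path.
#' @return `read_ct_matrix` returns `list(ct, assays)`.
#' @export
write_ct_matrix <- function(ct, assays, path) {
  role <- assays$role[match(rownames(ct), assays$assay)]
  d <- data.frame(assay = rownames(ct), role = role, ct,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_matrix
#' @export
read_ct_matrix <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ct <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(ct) <- d$assay
  list(ct = ct, assays = data.frame(assay = d$assay, role = d$role,
                                    stringsAsFactors = FALSE))
}

#' Read and write covariate tables
#'
#' @param covariates Covariate data frame (one row per participant).
#' @param path File path.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character"))
}

#' Read and write pool plans and selection results as JSON
#'
#' @param x Pool plan data frame ([make_pools()]) or selection list
#'   ([rank_and_select()]).
#' @param path File path.
#' @export
write_pools <- function(x, path) {
  jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pools
#' @export
read_pools <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname write_pools
#' @export
write_selection <- function(x, path) {
  jsonlite::write_json(list(top = x$top, selected = x$selected), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_pools
#' @export
read_selection <- function(path) {
  if (!file.exists(path)) {
    stop("selection file not found: ", path, call. = FALSE)
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a pipeline run configuration from YAML or JSON
#'
#' Every seed must be given explicitly; wall-clock seeding is refused.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  seeds <- grep("seed", names(cfg), value = TRUE)
  if (!length(seeds)) {
    stop("run configuration must set at least one explicit seed",
         call. = FALSE)
  }
  cfg
}
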