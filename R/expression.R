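#' Pool Ct values according to an RNA pool plan
#'
#' Simulates physical pooling of equal RNA masses: the pooled linear abundance
#' of each assay is the arithmetic mean of the members' linear abundances
#' (`2^-Ct`), so the pooled Ct is `-log2(mean(2^-Ct))`. Not-detected members
#' (`NA`) are excluded from the mean; an assay not detected in any member is
#' not detected in the pool.
#'
#' @param ct Numeric Ct matrix, rows = assays, columns = samples (column names
#'   are participant ids). `NA` marks not-detected.
#' @param pools Pool plan data frame from [make_pools()] (columns `pool_id`,
#'   `participant_id`).
#' @return Ct matrix with one column per pool.
#' @export
pool_ct <- function(ct, pools) {
  missing_members <- setdiff(pools$participant_id, colnames(ct))
  if (length(missing_members)) {
    stop("pool member(s) absent from Ct matrix: ",
         paste(missing_members, collapse = ", "), call. = FALSE)
  }
  pool_ids <- unique(pools$pool_id)
  out <- vapply(pool_ids, function(p) {
    members <- pools$participant_id[pools$pool_id == p]
    lin <- 2^-ct[, members, drop = FALSE]
    m <- rowMeans(lin, na.rm = TRUE)
    m[!is.finite(m)] <- NA_real_  # all members not detected
    -log2(m)
  }, numeric(nrow(ct)))
  matrix(out, nrow = nrow(ct),
         dimnames = list(rownames(ct), pool_ids))
}

#' Relative expression from Ct values
#'
#' Per sample (column), computes `dCt = Ct(target) - mean Ct(controls)` and
#' returns relative expression `2^-dCt` for the target assays. The control set
#' depends on the assay stage: the array-control panel for screening, the
#' SNORD61 and cel-miR-39 assays for validation.
#'
#' @param ct Numeric Ct matrix (rows = assays, columns = samples/pools).
#' @param assays Data frame describing the rows of `ct`: columns `assay`
#'   (matching `rownames(ct)`) and `role` in `"target"`, `"array_control"`,
#'   `"snord61"`, `"cel_mir_39"`.
#' @param stage `"screening"` (normalize to array controls) or `"validation"`
#'   (normalize to SNORD61 + cel-miR-39).
#' @return Matrix of relative expression (linear `2^-dCt` scale), rows =
#'   target assays, same columns as `ct`. Not-detected targets are `NA`.
#' @export
relative_expression <- function(ct, assays, stage = c("screening", "validation")) {
  stage <- match.arg(stage)
  if (!all(rownames(ct) %in% assays$assay)) {
    stop("all Ct rows must be annotated in `assays`", call. = FALSE)
  }
  role <- assays$role[match(rownames(ct), assays$assay)]
  ctrl_roles <- if (stage == "screening") "array_control" else
    c("snord61", "cel_mir_39")
  ctrl <- role %in% ctrl_roles
  if (!any(ctrl)) {
    stop("no control assays present for stage '", stage, "'", call. = FALSE)
  }
  ctrl_mean <- colMeans(ct[ctrl, , drop = FALSE], na.rm = TRUE)
  bad <- !is.finite(ctrl_mean)
  if (any(bad)) {
    stop("no usable control Ct in column(s): ",
         paste(colnames(ct)[bad], collapse = ", "), call. = FALSE)
  }
  targ <- role == "target"
  dct <- sweep(ct[targ, , drop = FALSE], 2L, ctrl_mean, `-`)
  expr <- 2^-dct
  attr(expr, "stage") <- stage
  expr
}
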