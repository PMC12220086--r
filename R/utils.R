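# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from the global seed
#'
#' One global seed fans out deterministically to named pipeline stages so
#' each stage can be re-run in isolation with identical randomness.
#'
#' @param seed integer global seed.
#' @param stage stage name, one of the pipeline stage labels.
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stages <- c("simulate", "doses", "cohorts", "pgs_assoc", "gwas",
              "enrich", "variance", "icd")
  idx <- match(stage, stages)
  if (is.na(idx)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 131L + idx * 9973) %% 2147483647)
}

assert_cols <- function(dt, cols, what = "input") {
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

as_dt <- function(x) {
  if (!data.table::is.data.table(x)) data.table::as.data.table(x) else data.table::copy(x)
}
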