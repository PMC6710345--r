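#' Round half away from zero
#'
#' Display rounding used for report tables: ties round up in absolute value
#' (so 0.005 -> 0.01), matching how the summary tables are printed. Internal
#' computations are never rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("resistrisk_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("resistrisk_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# columns of a sample table that are not measurements
.id_cols <- c("sample_id", "site")

.value_cols <- function(df) setdiff(names(df), .id_cols)

.check_sample_table <- function(df, what = "table") {
  if (!is.data.frame(df)) stop_validation(what, " must be a data.frame")
  miss <- setdiff(.id_cols, names(df))
  if (length(miss) > 0)
    stop_validation(what, " lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_validation(what, " has duplicated sample_id values")
  invisible(df)
}
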