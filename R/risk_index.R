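#' Metal reference table (background values and toxic-response factors)
#'
#' A reference set pairs each metal with its regional soil background
#' concentration (mg/kg dry soil) and its Hakanson toxic-response factor, the
#' dimensionless weight expressing how biologically hazardous the metal is
#' (Zn 1 < Cr 2 < Cu = Pb = Ni 5 < As 10 < Cd 30).
#'
#' @param metal character vector of metal identifiers.
#' @param background_value positive background concentrations (mg/kg).
#' @param toxic_response positive dimensionless toxic-response factors.
#' @return a validated `data.frame` with the three columns above.
#' @export
metal_reference <- function(metal, background_value, toxic_response) {
  ref <- data.frame(metal = as.character(metal),
                    background_value = as.numeric(background_value),
                    toxic_response = as.numeric(toxic_response),
                    stringsAsFactors = FALSE)
  validate_metal_reference(ref)
}

#' @rdname metal_reference
#' @param ref a data.frame with columns `metal`, `background_value`,
#'   `toxic_response`.
#' @export
validate_metal_reference <- function(ref) {
  need <- c("metal", "background_value", "toxic_response")
  miss <- setdiff(need, names(ref))
  if (length(miss) > 0)
    stop_validation("reference table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ref$metal))
    stop_validation("duplicated metals in reference table")
  if (any(!is.finite(ref$background_value)) || any(ref$background_value <= 0))
    stop_validation("background values must be positive and finite")
  if (any(!is.finite(ref$toxic_response)) || any(ref$toxic_response <= 0))
    stop_validation("toxic-response factors must be positive and finite")
  ref
}

#' Built-in metal reference profiles
#'
#' `"default"` carries the textbook Hakanson toxic-response ordering
#' (Zn 1, Cr 2, Cu/Pb/Ni 5, As 10, Cd 30) with the study region's soil
#' background values. `"table2-compat"` differs only in Tr(Ni) = 2: the
#' published per-site Ni risk factors are arithmetically consistent only with
#' that value, so both profiles ship and the choice is explicit.
#'
#' @param profile `"default"` or `"table2-compat"`.
#' @return a metal reference `data.frame` (see [metal_reference()]).
#' @export
hakanson_reference <- function(profile = c("default", "table2-compat")) {
  profile <- match.arg(profile)
  file <- system.file("extdata",
                      if (profile == "default") "metal_reference.csv"
                      else "metal_reference_table2_compat.csv",
                      package = "resistrisk", mustWork = TRUE)
  validate_metal_reference(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' Read and validate a concentration table
#'
#' @param file CSV with columns `sample_id`, `site`, then one column per metal
#'   in mg/kg dry soil.
#' @return a validated concentration `data.frame`.
#' @export
read_concentrations <- function(file) {
  validate_concentrations(utils::read.csv(file, stringsAsFactors = FALSE,
                                          check.names = FALSE))
}

#' @rdname read_concentrations
#' @param conc concentration data.frame.
#' @export
validate_concentrations <- function(conc) {
  .check_sample_table(conc, "concentration table")
  metals <- .value_cols(conc)
  if (length(metals) == 0) stop_validation("no metal columns present")
  if (nrow(conc) == 0) stop_validation("empty concentration table")
  vals <- as.matrix(conc[metals])
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop_validation("concentrations must be finite numbers")
  if (any(vals < 0)) stop_validation("negative concentration found")
  conc
}

.match_reference <- function(metals, ref) {
  miss <- setdiff(metals, ref$metal)
  if (length(miss) > 0)
    stop_config("no reference entry for metal(s): ", paste(miss, collapse = ", "))
  ref[match(metals, ref$metal), , drop = FALSE]
}

#' Contamination factors (Cf)
#'
#' Cf is the single-metal pollution index: measured concentration divided by
#' the background concentration, per sample and metal.
#'
#' @param conc concentration table (`sample_id`, `site`, metal columns).
#' @param ref metal reference table (see [metal_reference()]).
#' @return data.frame of the same shape with Cf values in the metal columns.
#' @export
contamination_factor <- function(conc, ref) {
  conc <- validate_concentrations(conc)
  ref <- validate_metal_reference(ref)
  metals <- .value_cols(conc)
  r <- .match_reference(metals, ref)
  out <- conc
  out[metals] <- as.data.frame(sweep(as.matrix(conc[metals]), 2,
                                     r$background_value, `/`),
                               check.names = FALSE)
  out
}

#' Monomial potential ecological risk factors (Er)
#'
#' Er weights each contamination factor by the metal's toxic-response factor:
#' Er = Tr * Cf.
#'
#' @param cf contamination-factor table from [contamination_factor()].
#' @param ref the same metal reference table used to compute `cf`.
#' @return data.frame of the same shape with Er values.
#' @export
monomial_risk <- function(cf, ref) {
  .check_sample_table(cf, "Cf table")
  ref <- validate_metal_reference(ref)
  metals <- .value_cols(cf)
  r <- .match_reference(metals, ref)
  out <- cf
  out[metals] <- as.data.frame(sweep(as.matrix(cf[metals]), 2,
                                     r$toxic_response, `*`),
                               check.names = FALSE)
  out
}

#' Integrated potential ecological risk index (RI)
#'
#' RI for a sample is the sum of its monomial risk factors over all metals in
#' the panel.
#'
#' @param er Er table from [monomial_risk()].
#' @param metals metals to sum over; defaults to every metal column present.
#' @param allow_missing if `TRUE`, metals listed but absent from `er` are
#'   dropped with a message instead of an error.
#' @return data.frame with columns `sample_id`, `site`, `RI`.
#' @export
risk_index <- function(er, metals = NULL, allow_missing = FALSE) {
  .check_sample_table(er, "Er table")
  have <- .value_cols(er)
  metals <- metals %||% have
  miss <- setdiff(metals, have)
  if (length(miss) > 0) {
    if (!allow_missing)
      stop_validation("missing Er value(s) for metal(s): ",
                      paste(miss, collapse = ", "),
                      " (set allow_missing = TRUE to exclude)")
    message("excluding metal(s) with no Er values: ", paste(miss, collapse = ", "))
    metals <- setdiff(metals, miss)
  }
  data.frame(sample_id = er$sample_id, site = er$site,
             RI = rowSums(as.matrix(er[metals])),
             stringsAsFactors = FALSE)
}

#' Compute the full risk result for a concentration table
#'
#' Convenience wrapper: Cf, Er and RI in one pass.
#'
#' @inheritParams contamination_factor
#' @return list with elements `cf`, `er`, `ri` (see the individual functions).
#' @export
compute_risk <- function(conc, ref) {
  cf <- contamination_factor(conc, ref)
  er <- monomial_risk(cf, ref)
  list(cf = cf, er = er, ri = risk_index(er))
}

#' Per-site mean and standard deviation
#'
#' Summarises each value column per site as arithmetic mean and sample
#' standard deviation (denominator n - 1). A single-sample site has an
#' undefined dispersion, reported as `NA`.
#'
#' @param df a sample table (`sample_id`, `site`, value columns).
#' @param cols value columns to summarise; default all.
#' @return long data.frame with columns `site`, `variable`, `n`, `mean`, `sd`.
#' @export
site_summary <- function(df, cols = NULL) {
  .check_sample_table(df, "value table")
  cols <- cols %||% .value_cols(df)
  if (length(df$site) == 0) stop_validation("no samples")
  sites <- unique(df$site)
  out <- do.call(rbind, lapply(sites, function(s) {
    sub <- df[df$site == s, , drop = FALSE]
    data.frame(site = s, variable = cols, n = nrow(sub),
               mean = vapply(cols, function(v) mean(sub[[v]]), 0),
               sd = vapply(cols, function(v)
                 if (nrow(sub) < 2) NA_real_ else stats::sd(sub[[v]]), 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Per-metal contribution to the integrated risk index
#'
#' The contribution of a metal is its Er averaged over sites, as a percentage
#' of the RI averaged over sites. With `weighted = FALSE` (default) each site
#' counts once regardless of its sample size (mean of site means); with
#' `weighted = TRUE` sites are weighted by their sample counts.
#'
#' @param site_er_means data.frame `site`, `metal`, `mean` (per-site Er means),
#'   or a wide data.frame with a `site` column and one column per metal.
#' @param site_ri_means data.frame `site`, `mean` (per-site RI means).
#' @param weights optional per-site sample counts (named by site) for the
#'   weighted variant.
#' @return named numeric vector of percentages, one per metal.
#' @export
contribution_to_ri <- function(site_er_means, site_ri_means, weights = NULL) {
  if (!"mean" %in% names(site_er_means) && "site" %in% names(site_er_means)) {
    metals <- setdiff(names(site_er_means), "site")
    site_er_means <- data.frame(
      site = rep(site_er_means$site, times = length(metals)),
      metal = rep(metals, each = nrow(site_er_means)),
      mean = unlist(site_er_means[metals], use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  if (!setequal(unique(site_er_means$site), site_ri_means$site))
    stop_validation("Er and RI summaries cover different site sets")
  w <- if (is.null(weights)) stats::setNames(rep(1, nrow(site_ri_means)),
                                             site_ri_means$site)
       else weights[as.character(site_ri_means$site)]
  ri_grand <- sum(site_ri_means$mean * w) / sum(w)
  if (!is.finite(ri_grand) || ri_grand == 0)
    stop_validation("mean RI over sites is zero; contributions undefined")
  metals <- unique(site_er_means$metal)
  pct <- vapply(metals, function(m) {
    sub <- site_er_means[site_er_means$metal == m, , drop = FALSE]
    wm <- w[as.character(sub$site)]
    100 * (sum(sub$mean * wm) / sum(wm)) / ri_grand
  }, 0)
  stats::setNames(pct, metals)
}

#' Site-level risk summary table
#'
#' Builds the publication-style summary: one row per metal with per-site
#' "mean +/- sd" Er values, an RI row, and a contribution column.
#'
#' @inheritParams compute_risk
#' @param digits display decimals for the formatted table.
#' @return list with `er_summary`, `ri_summary` (long summaries),
#'   `contribution` (named percentages) and `formatted` (character table).
#' @export
risk_site_table <- function(conc, ref, digits = 2) {
  res <- compute_risk(conc, ref)
  metals <- .value_cols(res$er)
  ers <- site_summary(res$er)
  ris <- site_summary(res$ri)
  contrib <- contribution_to_ri(
    site_er_means = stats::setNames(ers[c("site", "variable", "mean")],
                                    c("site", "metal", "mean")),
    site_ri_means = ris[c("site", "mean")])
  sites <- unique(ers$site)
  fmt_cell <- function(m, s) {
    paste0(round_half_up(m, digits),
           ifelse(is.na(s), "", paste0(" ± ", round_half_up(s, digits))))
  }
  rows <- lapply(metals, function(mt) {
    sub <- ers[ers$variable == mt, ]
    cells <- fmt_cell(sub$mean[match(sites, sub$site)],
                      sub$sd[match(sites, sub$site)])
    c(stats::setNames(cells, sites),
      contribution = paste0(round_half_up(contrib[[mt]], digits), "%"))
  })
  ri_cells <- fmt_cell(ris$mean[match(sites, ris$site)],
                       ris$sd[match(sites, ris$site)])
  formatted <- rbind(do.call(rbind, rows),
                     c(stats::setNames(ri_cells, sites), contribution = "-"))
  rownames(formatted) <- c(paste0("RI-", metals), "RI")
  list(er_summary = ers, ri_summary = ris, contribution = contrib,
       formatted = as.data.frame(formatted, stringsAsFactors = FALSE))
}
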