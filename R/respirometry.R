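#' Oxygen-consumption rate of a trace segment
#'
#' Least-squares slope of the O2 trace within a time segment, sign-flipped
#' (consumption decreases O2) and normalized to 1e6 cells. Units follow the
#' input: with O2 in ngAO and time in minutes the rate is
#' ngAO min^-1 (1e6 cells)^-1.
#'
#' @param times Time points (strictly increasing within the segment).
#' @param o2 O2 readings, same length as `times`.
#' @param from,to Segment bounds (inclusive); default the full trace.
#' @param cells Number of cells in the chamber (default 1e6).
#'
#' @return The segment rate (a single number).
#' @export
#' @examples
#' t <- 0:10
#' segment_rate(t, 100 - 5.2 * t) # 5.2
segment_rate <- function(times, o2, from = -Inf, to = Inf, cells = 1e6) {
  if (length(times) != length(o2)) {
    abort("`times` and `o2` must have the same length.",
          class = "spheroseq_input_error")
  }
  sel <- times >= from & times <= to
  t_seg <- times[sel]; o_seg <- o2[sel]
  if (length(t_seg) < 3) {
    abort("A segment needs at least 3 points to fit a rate.",
          class = "spheroseq_insufficient_data_error")
  }
  if (is.unsorted(t_seg, strictly = TRUE)) {
    abort("Times must be strictly increasing within the segment.",
          class = "spheroseq_input_error")
  }
  slope <- coef(lm(o_seg ~ t_seg))[["t_seg"]]
  -slope / (cells / 1e6)
}

#' OxPhos flux
#'
#' Oxygen consumption coupled to ATP synthesis: the basal respiration rate
#' minus the rate remaining in the presence of oligomycin (an F1FO-ATP
#' synthase inhibitor). A negative flux (oligomycin rate above basal) is
#' returned as-is with a warning.
#'
#' @param basal,oligomycin Rates in ngAO min^-1 (1e6 cells)^-1; both >= 0.
#'
#' @return `basal - oligomycin` (vectorized).
#' @export
#' @examples
#' oxphos_flux(5.2, 1.7)  # 3.5, monolayer
#' oxphos_flux(10.3, 3)   # 7.3, spheroid
oxphos_flux <- function(basal, oligomycin) {
  if (any(basal < 0) || any(oligomycin < 0)) {
    abort("Rates must be non-negative.", class = "spheroseq_input_error")
  }
  flux <- basal - oligomycin
  if (any(flux < 0)) {
    warn("Oligomycin rate exceeds basal rate; negative OxPhos flux reported.")
  }
  flux
}

#' Mitochondrial coupling ratio (U/B.R.)
#'
#' Ratio of the CCCP-uncoupled (maximal) respiration to the basal rate; a
#' dimensionless estimate of mitochondrial coupling, >= 1 whenever the
#' uncoupler stimulates respiration.
#'
#' @param uncoupled Uncoupled respiration rate (U).
#' @param basal Basal respiration rate (B.R.); must be > 0.
#'
#' @return `uncoupled / basal` (vectorized).
#' @export
#' @examples
#' uncoupling_ratio(17.2, 10.3) # ~1.67, rounds to 1.7
uncoupling_ratio <- function(uncoupled, basal) {
  if (any(basal <= 0)) {
    abort("Basal rate must be positive.", class = "spheroseq_division_error")
  }
  uncoupled / basal
}

#' Geometric-mean spheroid diameter
#'
#' `D_G = sqrt(a * b)` of two orthogonal diameters; symmetric in `a` and `b`
#' and always between them.
#'
#' @param a,b Orthogonal diameters in micrometers; both > 0.
#'
#' @return D_G in micrometers (vectorized).
#' @export
#' @examples
#' geometric_mean_diameter(100, 400) # 200
geometric_mean_diameter <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) {
    abort("Diameters must be positive.", class = "spheroseq_input_error")
  }
  sqrt(a * b)
}

#' Per-replicate respirometry profile
#'
#' Derives the OxPhos quantities from one replicate's four segment rates:
#' OxPhos flux (basal - oligomycin), uncoupling ratio (U/B.R.), and the
#' non-mitochondrial fraction (NaCN-resistant rate / basal). With
#' `nonmito_correction = TRUE` the NaCN-resistant rate is subtracted from the
#' basal, oligomycin and uncoupled rates before the derived quantities are
#' formed (off by default). A NaCN rate above basal triggers a warning.
#'
#' @param basal,oligomycin,cccp,nacn Segment rates in
#'   ngAO min^-1 (1e6 cells)^-1 (vectorized over replicates).
#' @param nonmito_correction Subtract the NaCN-resistant rate first
#'   (default `FALSE`).
#'
#' @return A tibble with the four input rates plus `oxphos_flux`,
#'   `uncoupling_ratio`, `nonmito_fraction`.
#' @export
respirometry_profile <- function(basal, oligomycin, cccp, nacn = 0,
                                 nonmito_correction = FALSE) {
  if (any(c(basal, oligomycin, cccp, nacn) < 0)) {
    abort("Rates must be non-negative.", class = "spheroseq_input_error")
  }
  if (any(nacn > basal)) {
    warn("NaCN-resistant rate exceeds basal rate in at least one replicate.")
  }
  b <- basal; o <- oligomycin; u <- cccp
  if (nonmito_correction) {
    b <- pmax(basal - nacn, 0)
    o <- pmax(oligomycin - nacn, 0)
    u <- pmax(cccp - nacn, 0)
  }
  tibble(
    basal = basal, oligomycin = oligomycin, cccp = cccp, nacn = nacn,
    oxphos_flux = oxphos_flux(b, o),
    uncoupling_ratio = uncoupling_ratio(u, b),
    nonmito_fraction = nacn / basal
  )
}

.p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "", p < 0.0005 ~ "***", p < 0.005 ~ "**", p < 0.05 ~ "*",
    .default = ""
  )
}

#' Summarize replicate respirometry by condition
#'
#' Builds a Table-1-style summary from a replicate table: per condition and
#' measure, the mean and SD over replicates, plus a paired t-test between the
#' two conditions (replicates matched by `replicate`). Ratios are averaged
#' per replicate (mean of per-replicate ratios), the convention consistent
#' with the printed coupling ratios.
#'
#' @param replicates Tibble with columns `condition`, `replicate`, `basal`,
#'   `oligomycin`, `cccp`, and optionally `nacn`.
#' @param nonmito_correction Passed to [respirometry_profile()].
#'
#' @return A tibble with `measure`, one `mean_<condition>` / `sd_<condition>`
#'   pair per condition, `p_value` (paired t-test; `NA` when not exactly two
#'   conditions), and `stars`.
#' @export
summarize_respirometry <- function(replicates, nonmito_correction = FALSE) {
  needed <- c("condition", "replicate", "basal", "oligomycin", "cccp")
  missing_cols <- setdiff(needed, names(replicates))
  if (length(missing_cols)) {
    abort(paste0("`replicates` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "spheroseq_input_error")
  }
  nacn <- replicates[["nacn"]] %||% rep(0, nrow(replicates))
  prof <- dplyr::bind_cols(
    dplyr::select(replicates, "condition", "replicate"),
    respirometry_profile(replicates$basal, replicates$oligomycin,
                         replicates$cccp, nacn, nonmito_correction)
  )
  measures <- c("basal", "oligomycin", "cccp", "nacn",
                "oxphos_flux", "uncoupling_ratio", "nonmito_fraction")
  long <- prof |>
    tidyr::pivot_longer(dplyr::all_of(measures),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(measure = factor(.data$measure, levels = measures))

  wide <- long |>
    dplyr::group_by(.data$measure, .data$condition) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("mean", "sd"))

  conds <- unique(replicates$condition)
  pvals <- if (length(conds) == 2) {
    long |>
      dplyr::group_by(.data$measure) |>
      dplyr::group_modify(function(d, key) {
        paired <- tidyr::pivot_wider(d, id_cols = "replicate",
                                     names_from = "condition",
                                     values_from = "value")
        a <- paired[[conds[1]]]; b <- paired[[conds[2]]]
        ok <- complete.cases(a, b)
        p <- if (sum(ok) >= 2 && sd(a[ok] - b[ok]) > 0) {
          t.test(a[ok], b[ok], paired = TRUE)$p.value
        } else NA_real_
        tibble(p_value = p)
      }) |>
      dplyr::ungroup()
  } else {
    tibble(measure = factor(measures, levels = measures), p_value = NA_real_)
  }

  wide |>
    dplyr::left_join(pvals, by = "measure") |>
    dplyr::mutate(measure = as.character(.data$measure),
                  stars = .p_stars(.data$p_value))
}
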