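# Dual-mode lipolytic screening: Rhodamine-olive-oil agar halo scores plus
# extracellular activity measured in olive-oil liquid cultures.
#
# A screening table is a plain data.frame with columns
#   strain   - unique label
#   roa_24h, roa_48h - halo scores, ordered factors none < partial < full
#                      (the "-", "+", "++" plate notation)
#   olm_48h, olm_72h - activities in nkat/mL, NA meaning *not detected*
#                      (distinct from a measured 0.000)

HALO_LEVELS <- c("none", "partial", "full")

.halo_factor <- function(x) {
  x <- as.character(x)
  map <- c("-" = "none", "+" = "partial", "++" = "full",
           none = "none", partial = "partial", full = "full")
  if (any(!x %in% names(map)))
    stop("halo scores must be one of -, +, ++ (or none/partial/full)",
         call. = FALSE)
  factor(map[x], levels = HALO_LEVELS, ordered = TRUE)
}

#' Build a validated screening table
#'
#' @param strain character vector of unique strain ids.
#' @param roa_24h,roa_48h Rhodamine-plate halo scores at 24 h / 48 h, given as
#'   `-` / `+` / `++` or `none` / `partial` / `full`.
#' @param olm_48h,olm_72h extracellular activities (nkat/mL) in olive-oil
#'   liquid medium at 48 h / 72 h; `NA` means not detected, which is distinct
#'   from a measured 0.
#' @return data.frame of class `screening_table`.
#' @seealso [santorini_screen()] for the packaged 101-strain table.
#' @export
screening_table <- function(strain, roa_24h, roa_48h, olm_48h, olm_72h) {
  strain <- as.character(strain)
  if (anyDuplicated(strain))
    stop("duplicate strain ids: ",
         paste(unique(strain[duplicated(strain)]), collapse = ", "),
         call. = FALSE)
  olm_48h <- as.numeric(olm_48h); olm_72h <- as.numeric(olm_72h)
  for (v in list(olm_48h, olm_72h)) {
    ok <- (is.na(v) & !is.nan(v)) | (is.finite(v) & v >= 0)
    if (!all(ok))
      stop("activities must be finite and >= 0 (or NA for not detected)",
           call. = FALSE)
  }
  df <- data.frame(strain = strain,
                   roa_24h = .halo_factor(roa_24h),
                   roa_48h = .halo_factor(roa_48h),
                   olm_48h = olm_48h, olm_72h = olm_72h,
                   stringsAsFactors = FALSE)
  class(df) <- c("screening_table", "data.frame")
  df
}

#' Read/write screening tables
#'
#' CSV dialect: columns `strain, roa_24h, roa_48h, olm_48h, olm_72h`; halo
#' scores as `-`/`+`/`++`, non-detected activities as the sentinel `ND`.
#'
#' @param path file path.
#' @param x a screening table (for writing).
#' @return `read_screening_csv()` a `screening_table`;
#'   `write_screening_csv()` the path, invisibly.
#' @export
read_screening_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("strain", "roa_24h", "roa_48h", "olm_48h", "olm_72h")
  if (!all(need %in% names(df)))
    stop("screening CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  nd <- function(v) ifelse(v %in% c("ND", "nd", ""), NA, v)
  screening_table(df$strain, df$roa_24h, df$roa_48h,
                  as.numeric(nd(df$olm_48h)), as.numeric(nd(df$olm_72h)))
}

#' @rdname read_screening_csv
#' @export
write_screening_csv <- function(x, path) {
  sym <- c(none = "-", partial = "+", full = "++")
  out <- data.frame(strain = x$strain,
                    roa_24h = sym[as.character(x$roa_24h)],
                    roa_48h = sym[as.character(x$roa_48h)],
                    olm_48h = ifelse(is.na(x$olm_48h), "ND",
                                     format(x$olm_48h, trim = TRUE)),
                    olm_72h = ifelse(is.na(x$olm_72h), "ND",
                                     format(x$olm_72h, trim = TRUE)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' p-nitrophenyl palmitate assay configuration
#'
#' Geometry and calibration of the chromogenic lipase assay: 950 uL substrate
#' solution plus 50 uL sample, 15 min incubation, p-nitrophenol read at
#' 410 nm against a per-pH calibration curve.
#'
#' @param reaction_volume total reaction volume in mL.
#' @param sample_volume sample volume in mL.
#' @param incubation_time incubation in seconds.
#' @param calib_slope calibration slope in absorbance units per nmol of
#'   p-nitrophenol in the reaction.
#' @return list of class `assay_config`.
#' @export
assay_config <- function(reaction_volume = 1.0, sample_volume = 0.05,
                         incubation_time = 900, calib_slope = 0.01) {
  vals <- c(reaction_volume, sample_volume, incubation_time, calib_slope)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all assay parameters must be strictly positive", call. = FALSE)
  structure(list(reaction_volume = reaction_volume,
                 sample_volume = sample_volume,
                 incubation_time = incubation_time,
                 calib_slope = calib_slope),
            class = "assay_config")
}

#' Convert assay absorbance to lipase activity
#'
#' Blank-corrected A410 is converted to nmol of p-nitrophenol released via the
#' calibration slope, then to nanokatal (nmol/s) per mL of sample:
#' `activity = (a410 - blank) / calib_slope / incubation_time / sample_volume`.
#' A reading below its blank is clamped to zero activity.
#'
#' @param a410 absorbance at 410 nm (vectorised).
#' @param blank blank absorbance (heat-inactivated sample).
#' @param config an [assay_config()].
#' @return activity in nkat/mL.
#' @examples
#' activity_from_absorbance(0.5, 0, assay_config(calib_slope = 0.01))
#' @export
activity_from_absorbance <- function(a410, blank = 0, config = assay_config()) {
  stopifnot(inherits(config, "assay_config"))
  pnp_nmol <- pmax(a410 - blank, 0) / config$calib_slope
  pnp_nmol / config$incubation_time / config$sample_volume
}

# mean of the available liquid activities; NA when both are non-detected
.liquid_mean <- function(a48, a72) {
  m <- rowMeans(cbind(a48, a72), na.rm = TRUE)
  m[is.na(a48) & is.na(a72)] <- NA_real_
  m
}

#' Classify strains from liquid-culture activities
#'
#' A strain is `none` when activity was detected at neither time point
#' (both entries non-detected), otherwise `significant` when the mean of the
#' available 48 h / 72 h activities exceeds 0.05 nkat/mL and `low` when it is
#' detectable but at or below that threshold. A measured 0.000 counts as a
#' value in the mean; a non-detected entry paired with a numeric one
#' contributes nothing.
#'
#' @param records a [screening_table()].
#' @param threshold significance threshold in nkat/mL (strict inequality).
#' @return factor with levels `none`, `low`, `significant` (one per strain).
#' @export
classify_liquid <- function(records, threshold = 0.05) {
  m <- .liquid_mean(records$olm_48h, records$olm_72h)
  out <- ifelse(is.na(m), "none", ifelse(m > threshold, "significant", "low"))
  factor(out, levels = c("none", "low", "significant"))
}

#' Classify strains from plate halos
#'
#' @param records a [screening_table()].
#' @return logical: TRUE when a fluorescent halo (partial or full) was scored
#'   at either 24 h or 48 h.
#' @export
classify_halo <- function(records) {
  records$roa_24h > "none" | records$roa_48h > "none"
}

# round half away from zero to `digits` decimals (commercial rounding, used
# for the reported percentages)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarise a screening table
#'
#' Counts (and percentages, rounded half-up to one decimal) of halo producers
#' and of the three liquid-culture classes.
#'
#' @param records a [screening_table()].
#' @param threshold liquid significance threshold in nkat/mL.
#' @return list of class `screen_summary` with `n_total`, `n_halo`,
#'   `n_significant`, `n_low`, `n_none`, `n_detectable`
#'   (= significant + low) and matching `pct_*` fields.
#' @examples
#' summarize_screen(santorini_screen())
#' @export
summarize_screen <- function(records, threshold = 0.05) {
  if (nrow(records) == 0) stop("empty screening table", call. = FALSE)
  if (anyDuplicated(records$strain))
    stop("duplicate strain ids", call. = FALSE)
  cls <- classify_liquid(records, threshold)
  n <- nrow(records)
  counts <- table(cls)
  pct <- function(k) round_half_up(100 * k / n, 1)
  n_halo <- sum(classify_halo(records))
  out <- list(n_total = n, n_halo = n_halo,
              n_significant = unname(counts["significant"]),
              n_low = unname(counts["low"]),
              n_none = unname(counts["none"]),
              n_detectable = unname(counts["significant"] + counts["low"]),
              pct_halo = pct(n_halo),
              pct_significant = pct(unname(counts["significant"])),
              pct_low = pct(unname(counts["low"])),
              pct_none = pct(unname(counts["none"])),
              pct_detectable = pct(unname(counts["significant"] + counts["low"])),
              threshold = threshold)
  class(out) <- "screen_summary"
  out
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("<screen_summary> %d strains\n", x$n_total))
  cat(sprintf("  halo producers:        %3d (%.1f%%)\n", x$n_halo, x$pct_halo))
  cat(sprintf("  liquid > %.3g nkat/mL: %3d (%.1f%%)\n", x$threshold,
              x$n_significant, x$pct_significant))
  cat(sprintf("  liquid low:            %3d (%.1f%%)\n", x$n_low, x$pct_low))
  cat(sprintf("  no activity:           %3d (%.1f%%)\n", x$n_none, x$pct_none))
  invisible(x)
}

#' Select strains for follow-up characterisation
#'
#' Applies the bioprospecting selection rule: keep strains whose mean liquid
#' activity exceeds `activity_threshold`, plus (when `require_full_halo`)
#' strains with an intense (full-coverage, `++`) halo at either time point.
#'
#' @param records a [screening_table()].
#' @param activity_threshold nkat/mL, strict inequality (default 0.75).
#' @param require_full_halo include full-halo producers regardless of their
#'   liquid activity.
#' @return sorted character vector of selected strain ids.
#' @export
select_strains <- function(records, activity_threshold = 0.75,
                           require_full_halo = TRUE) {
  m <- .liquid_mean(records$olm_48h, records$olm_72h)
  keep <- !is.na(m) & m > activity_threshold
  if (require_full_halo)
    keep <- keep | records$roa_24h == "full" | records$roa_48h == "full"
  sort(records$strain[keep])
}

#' Packaged Santorini screening and kinetics tables
#'
#' Reference data shipped with the package: the dual-mode screening outcomes
#' of the 101 thermophilic bacterial strains isolated near the Santorini
#' volcano (`santorini_screen()`), the published two-step deactivation
#' parameters of the nine selected lipases at 70-100 degrees C
#' (`santorini_deact_params()`), and the corresponding published activation
#' energies (`santorini_activation_energies()`).
#'
#' @return `santorini_screen()` a [screening_table()];
#'   the other two, plain data.frames.
#' @examples
#' summarize_screen(santorini_screen())
#' @export
santorini_screen <- function() {
  read_screening_csv(system.file("extdata", "santorini_screen.csv",
                                 package = "thermolipase", mustWork = TRUE))
}

#' @rdname santorini_screen
#' @export
santorini_deact_params <- function() {
  utils::read.csv(system.file("extdata", "santorini_deact_params.csv",
                              package = "thermolipase", mustWork = TRUE))
}

#' @rdname santorini_screen
#' @export
santorini_activation_energies <- function() {
  utils::read.csv(system.file("extdata", "santorini_activation_energies.csv",
                              package = "thermolipase", mustWork = TRUE))
}
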