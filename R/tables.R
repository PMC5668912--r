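#' Packaged benchmark folding statistics for CLN025 and chignolin
#'
#' Transcribed aggregated native-state population curves (mean/SD/SE in
#' percent, integer-rounded as printed) and, where published, survival-based
#' folding-time estimates for sets of 20 independent 500-million-step NTP MD
#' folding simulations of the beta-hairpins CLN025 (FF14SB family, 277 K;
#' FF12MCstdm, 340 K) and chignolin (FF12MC family, 300 K).  Low-mass
#' conditions ran at dt = 1.00 fs with all atomic masses reduced tenfold and
#' are credited on the numerically equivalent standard-mass time axis
#' (`credit_fs = 3.16`).
#'
#' The files are validated against stored MD5 checksums and structural
#' invariants (row counts, `se <= sd`, aggregated time = N x steps x
#' credit), so any future correction is a data change, not a code change.
#'
#' @param validate verify checksums and invariants (default `TRUE`).
#' @return list with data frames `cln025` (4 conditions x 10 checkpoints)
#'   and `chignolin` (3 conditions x 22 checkpoints).  Columns: `condition`,
#'   `forcefield`, `temp_k`, `timestep_fs`, `credit_fs`, `steps_millions`,
#'   `agg_time_us`, `mean_pct`, `sd_pct`, `se_pct`, and for chignolin also
#'   `tau_ns`, `lcl_ns`, `ucl_ns`, `events` (NA where not published).
#' @export
benchmark_tables <- function(validate = TRUE) {
  f1 <- system.file("extdata", "benchmark_cln025.csv", package = "lmdk",
                    mustWork = TRUE)
  f2 <- system.file("extdata", "benchmark_chignolin.csv", package = "lmdk",
                    mustWork = TRUE)
  cln <- read.csv(f1, comment.char = "#")
  chig <- read.csv(f2, comment.char = "#")
  if (validate) {
    sums <- unname(tools::md5sum(c(f1, f2)))
    expected <- c("205d1d9fd7374a95016e31f2ac397667",
                  "584c44a8b82e113e6351d7242a7f2ed0")
    if (!identical(sums, expected))
      stop("benchmark table checksum mismatch; transcription corrupted?")
    stopifnot(
      nrow(cln) == 40, nrow(chig) == 66,
      all(table(cln$condition) == 10), all(table(chig$condition) == 22),
      all(cln$se_pct <= cln$sd_pct), all(chig$se_pct <= chig$sd_pct),
      all(cln$mean_pct >= 0 & cln$mean_pct <= 100),
      all(chig$mean_pct >= 0 & chig$mean_pct <= 100))
    agg <- function(d) max(abs(d$agg_time_us -
                                 20 * d$steps_millions * 1e6 * d$credit_fs / 1e9))
    stopifnot(agg(cln) < 0.005, agg(chig) < 0.005)
  }
  list(cln025 = cln, chignolin = chig)
}

#' Mean population curve for one benchmark condition
#'
#' @param table one of the data frames returned by [benchmark_tables()].
#' @param condition a `condition` label present in the table.
#' @return numeric vector of aggregated population means (percent), ordered
#'   by checkpoint.
#' @export
benchmark_curve <- function(table, condition) {
  rows <- table[table$condition == condition, ]
  if (nrow(rows) == 0)
    stop("unknown condition: ", condition, "; available: ",
         paste(unique(table$condition), collapse = ", "))
  rows$mean_pct[order(rows$steps_millions)]
}
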