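#' Bundled fixtures from the published threshold and wildtype-region tables
#'
#' Loads the packaged inputs: the sixteen-protein table of lengths and
#' proportions of functional sequences (with the published derived columns
#' for comparison and a `known_discrepancy` flag on the four rows whose
#' published derived values cannot be reproduced from their inputs), the
#' local-functionality model parameters for beta-lactamase, GFP and HisA
#' (including the beta-lactamase stepwise tolerance schedule), and the
#' shared constants (`A_t = 7.5` transitions per mutation and the 0.69
#' nonsynonymous fraction).
#'
#' @return A list of class `"fixture_set"` with elements `table2` (data
#'   frame of protein records), `table3` (named list of per-protein model
#'   parameters), and `constants`.
#' @examples
#' fx <- load_fixtures()
#' nrow(fx$table2)        # 16
#' fx$table3$gfp$length   # 236
#' @export
load_fixtures <- function() {
  t2_path <- system.file("extdata", "table2.tsv", package = "seqspace")
  t3_path <- system.file("extdata", "table3.json", package = "seqspace")
  if (t2_path == "" || t3_path == "")
    stop("packaged fixture files are missing; reinstall the package")
  table2 <- utils::read.delim(t2_path, stringsAsFactors = FALSE)
  if (nrow(table2) != 16 ||
      !all(c("name", "length", "p_fs", "known_discrepancy") %in%
           names(table2)))
    stop("fixture integrity error: table2.tsv is corrupted")
  t3 <- jsonlite::read_json(t3_path, simplifyVector = TRUE)
  structure(list(table2 = table2,
                 table3 = t3$proteins,
                 constants = t3$constants),
            class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat("seqspace fixtures:", nrow(x$table2), "protein records;",
      length(x$table3), "local-functionality models; A_t =",
      x$constants$A_t, "\n")
  invisible(x)
}

round1 <- function(x) round(x, 1)

#' Recompute the published tables and annotate agreement
#'
#' Rebuilds both published tables from their inputs: the sixteen-protein
#' threshold table (thresholds, biasing-ratio exponents, minimum
#' neighbourhood mutation counts and sequence identities) and the
#' wildtype-region table (per-protein threshold and maximum Hamming
#' distance from the hyper-exponential model, plus the stepwise-schedule
#' estimate for beta-lactamase). Each derived cell is compared against the
#' published value; mismatches are confined to rows flagged
#' `known_discrepancy` in the fixtures. A published biasing-ratio exponent
#' is accepted when it equals either the floor or the nearest-integer
#' rendering of `log10(R_b)` (the published table mixes the two).
#'
#' @param fixtures a [load_fixtures()] result (default loads the packaged
#'   set).
#' @return A list of class `"table_reproduction"`: `table2` (threshold
#'   report plus `match_*` columns), `table3` (one row per protein with
#'   computed and published values), `flagged` (names of discrepant rows).
#' @examples
#' rep <- reproduce_tables()
#' rep$table3
#' @export
reproduce_tables <- function(fixtures = load_fixtures()) {
  A_t <- fixtures$constants$A_t

  t2 <- threshold_table(fixtures$table2, A_t = A_t)
  printed <- fixtures$table2
  log_rb <- log10(t2$r_b)
  t2$match_p_th <- t2$p_th_2sf == printed$p_th_printed
  t2$match_r_b <- printed$r_b_exp_printed == floor(log_rb) |
    printed$r_b_exp_printed == round(log_rb)
  t2$match_n_min <- t2$n_min == printed$n_min_printed
  t2$match_si <- t2$si_pct == printed$si_printed

  one3 <- function(key) {
    p <- fixtures$table3[[key]]
    p_th <- percolation_threshold(p$length, A_t)
    model <- hyperexp_model(p$alpha, p$beta)
    nmax_model <- n_max_from_model(model, p_th)
    nmax_sched <- if (!is.null(p$schedule))
      n_max_from_schedule(unlist(p$schedule), p_th) else NA_integer_
    n_lo <- if (is.na(nmax_sched)) nmax_model else min(nmax_sched, nmax_model)
    n_hi <- if (is.na(nmax_sched)) nmax_model else max(nmax_sched, nmax_model)
    data.frame(
      name = p$name, length = p$length,
      p_th = signif(p_th, 2),
      n_max_model = as.integer(nmax_model),
      n_max_schedule = nmax_sched,
      n_max = if (n_lo == n_hi) as.character(n_lo)
              else paste0(n_lo, "-", n_hi),
      si = if (n_lo == n_hi)
        paste0(round1(sequence_identity(n_lo, p$length)), "%")
      else paste0(round1(sequence_identity(n_hi, p$length)), "-",
                  round1(sequence_identity(n_lo, p$length)), "%"),
      p_th_printed = p$printed$p_th,
      n_max_printed = p$printed$n_max,
      stringsAsFactors = FALSE)
  }
  t3 <- do.call(rbind, lapply(names(fixtures$table3), one3))
  t3$match_p_th <- t3$p_th == t3$p_th_printed
  t3$match_n_max <- t3$n_max == t3$n_max_printed

  flagged <- t2$name[t2$known_discrepancy]
  mism <- t2$name[!(t2$match_p_th & t2$match_r_b & t2$match_n_min &
                      t2$match_si)]
  structure(list(table2 = t2, table3 = t3, flagged = flagged,
                 unexplained = setdiff(mism, flagged)),
            class = "table_reproduction")
}

#' @export
print.table_reproduction <- function(x, ...) {
  cat("Threshold table (computed vs published):\n")
  t2 <- as.data.frame(unclass(x$table2))
  print(t2[, c("name", "p_th_2sf", "r_b_exponent", "n_min", "si_pct",
               "match_p_th", "match_r_b", "match_n_min", "match_si")],
        row.names = FALSE)
  cat("\nWildtype-region table:\n")
  print(x$table3[, c("name", "length", "p_th", "n_max", "si",
                     "match_p_th", "match_n_max")], row.names = FALSE)
  cat("\nFlagged discrepant rows:", paste(x$flagged, collapse = ", "), "\n")
  if (length(x$unexplained))
    cat("Unflagged mismatches (unexpected):",
        paste(x$unexplained, collapse = ", "), "\n")
  invisible(x)
}

#' Write a run manifest alongside an output file
#'
#' Records the command, configuration digest, seed and package version so
#' that an output can be regenerated exactly.
#'
#' @param path manifest path (JSON).
#' @param command free-text command description.
#' @param config list of parameters that determined the run.
#' @param seed the seed used, if any.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), seed = NULL) {
  manifest <- list(
    command = command,
    config = config,
    config_digest = sum(utf8ToInt(paste(
      deparse(config, control = "all"), collapse = ""))),
    seed = seed,
    package_version = as.character(utils::packageVersion("seqspace")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
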