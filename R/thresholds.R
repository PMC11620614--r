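#' Percolation threshold of a substitution neighbourhood
#'
#' Approximates the site-percolation threshold of protein sequence space as
#' the reciprocal of the neighbour count. A sequence of `L` residues has on
#' average `A_t * L` single-mutation neighbours; allowing up to `n_m`
#' mutations between neighbours multiplies the count to `(A_t*L)^n_m / n_m!`,
#' so the threshold is
#' \deqn{P_{th} \approx \frac{n_m!}{(A_t L)^{n_m}}.}
#' For `n_m = 1` this reduces to `1 / (A_t * L)`, the reciprocal of the
#' coordination number.
#'
#' Values are computed in log space (log-factorial via [lgamma()]) so large
#' `n_m` and `L` do not overflow. The result can exceed 1 for very small
#' `A_t * L`; no clamping is applied.
#'
#' @param L sequence length in residues (positive integer).
#' @param A_t average number of amino acids reachable from one amino acid by
#'   a single mutation. The genetic-code average is 7.5 (the default); an
#'   idealised simulator with full transitions uses `A - 1`.
#' @param n_m maximum number of mutations separating neighbouring sequences
#'   (positive integer, default 1).
#' @return The threshold proportion, a positive numeric scalar.
#' @examples
#' percolation_threshold(99)                  # chorismate mutase, ~0.0013
#' percolation_threshold(10, A_t = 6)         # simulator space L=10, A=7
#' percolation_threshold(99, n_m = 11)        # multi-mutation neighbourhood
#' @seealso [min_nm()], [biasing_ratio()], [threshold_table()]
#' @export
percolation_threshold <- function(L, A_t = 7.5, n_m = 1L) {
  stopifnot(is.numeric(L), is.numeric(A_t), is.numeric(n_m))
  if (any(L <= 0) || any(L != floor(L)))
    stop("`L` must be a positive integer")
  if (any(A_t <= 0)) stop("`A_t` must be positive")
  if (any(n_m < 1) || any(n_m != floor(n_m)))
    stop("`n_m` must be a positive integer")
  exp(lgamma(n_m + 1) - n_m * log(A_t * L))
}

#' Biasing ratio of threshold to functional proportion
#'
#' The ratio `R_b = P_th / P_fs` between the percolation threshold and a
#' protein's proportion of functional sequences. It measures how much the
#' local density of functional sequences must exceed the global proportion
#' for extensive continuous functional paths to exist: if `R_b = 100`, the
#' local proportion along a corridor must be at least 100-fold enriched.
#'
#' @param P_th percolation threshold (positive proportion).
#' @param P_fs proportion of functional sequences (positive proportion).
#' @return `P_th / P_fs`, a positive numeric.
#' @examples
#' biasing_ratio(percolation_threshold(99), 1e-23)  # ~1.3e20
#' @export
biasing_ratio <- function(P_th, P_fs) {
  stopifnot(is.numeric(P_th), is.numeric(P_fs))
  if (any(P_th <= 0)) stop("`P_th` must be positive")
  if (any(P_fs <= 0)) stop("`P_fs` must be positive")
  P_th / P_fs
}

#' Order of magnitude of a positive number
#'
#' Returns `floor(log10(x))`, guarded against floating-point drift so exact
#' powers of ten map to their exponent over a wide range.
#'
#' @param x positive numeric.
#' @return Integer exponent(s) of ten.
#' @examples
#' order_of_magnitude(1.35e20)  # 20
#' @export
order_of_magnitude <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x <= 0)) stop("`x` must be positive")
  e <- floor(log10(x))
  # guard the bin edges against log drift: require 10^e <= x < 10^(e+1)
  e <- ifelse(x < 10^e, e - 1, e)
  e <- ifelse(x >= 10^(e + 1), e + 1, e)
  as.integer(e)
}

#' Smallest neighbourhood size with threshold at or below P_fs
#'
#' Searches `n_m = 1, 2, ...` for the smallest neighbourhood mutation count
#' whose percolation threshold drops to (or, under the default rule,
#' approximates) the protein's proportion of functional sequences.
#'
#' Two criteria are available. `"approx"` (the default) accepts `n_m` when
#' `P_th(n_m) <= P_fs * 10^tol_decades`, i.e. the threshold approximates or
#' drops below `P_fs` within `tol_decades` orders of magnitude; with the
#' default half-decade tolerance this reproduces the published table for all
#' rows not flagged as discrepant. `"strict"` requires `P_th(n_m) <= P_fs`
#' exactly. All comparisons are made in log space.
#'
#' The threshold is not monotone in `n_m` forever (the factorial eventually
#' dominates), so the search is bounded by `max_nm` and fails loudly if no
#' `n_m` qualifies.
#'
#' @inheritParams percolation_threshold
#' @param P_fs proportion of functional sequences, in (0, 1].
#' @param max_nm upper bound of the search (default 200).
#' @param rule threshold-comparison criterion, `"approx"` or `"strict"`.
#' @param tol_decades tolerance in orders of magnitude for `"approx"`
#'   (default 0.5).
#' @return The smallest qualifying `n_m`, as an integer.
#' @examples
#' min_nm(99, P_fs = 1e-23)   # 11 mutations for chorismate mutase
#' min_nm(50, P_fs = 1e-8)    # 4 for membrane-embedding peptides
#' @export
min_nm <- function(L, A_t = 7.5, P_fs, max_nm = 200L,
                   rule = c("approx", "strict"), tol_decades = 0.5) {
  rule <- match.arg(rule)
  stopifnot(length(L) == 1, length(P_fs) == 1)
  if (P_fs <= 0 || P_fs > 1) stop("`P_fs` must be in (0, 1]")
  if (max_nm < 1) stop("`max_nm` must be at least 1")
  slack <- if (rule == "approx") tol_decades * log(10) else 0
  log_pfs <- log(P_fs)
  log_z <- log(A_t * L)
  for (n in seq_len(max_nm)) {
    if (lgamma(n + 1) - n * log_z <= log_pfs + slack)
      return(as.integer(n))
  }
  stop("no n_m <= ", max_nm, " brings the threshold to P_fs = ", P_fs,
       " (the factorial term eventually dominates); raise `max_nm` ",
       "only if a solution can exist")
}

#' Sequence identity at a Hamming distance
#'
#' Converts a Hamming distance `n` from a wildtype of length `L` to percent
#' sequence identity, `SI = 100 * (1 - n / L)`.
#'
#' @param n Hamming distance (mutation count), `0 <= n <= L`.
#' @param L sequence length in residues.
#' @return Percent identity in \[0, 100\].
#' @examples
#' sequence_identity(11, 99)  # 88.9
#' @export
sequence_identity <- function(n, L) {
  stopifnot(is.numeric(n), is.numeric(L))
  if (any(L < 1)) stop("`L` must be positive")
  if (any(n < 0) || any(n > L)) stop("`n` must lie in [0, L]")
  100 * (1 - n / L)
}

#' Threshold report for a table of proteins
#'
#' Computes, for each protein record, the percolation threshold, the biasing
#' ratio and its order of magnitude, the minimum neighbourhood mutation
#' count at which the threshold reaches the proportion of functional
#' sequences, and the sequence identity that mutation count implies.
#'
#' @param records a data frame with columns `name`, `length` and `p_fs`
#'   (`source` and `known_discrepancy` are carried through if present), one
#'   row per protein. See [load_fixtures()] for the bundled table.
#' @param A_t average amino-acid transitions per mutation (default 7.5).
#' @param n_m neighbourhood mutation count used for `P_th` (default 1).
#' @param max_nm,rule,tol_decades passed to [min_nm()].
#' @return A data frame of class `"threshold_report"` with columns `name`,
#'   `length`, `p_th`, `p_th_2sf`, `p_fs`, `r_b`, `r_b_exponent`, `n_min`,
#'   `si`, `si_pct` (integer-rounded), plus any carried metadata. Raw
#'   full-precision values are always retained; the `_2sf`/`_pct` columns
#'   are display renderings.
#' @examples
#' tab <- threshold_table(load_fixtures()$table2)
#' tab[, c("name", "p_th_2sf", "r_b_exponent", "n_min", "si_pct")]
#' @export
threshold_table <- function(records, A_t = 7.5, n_m = 1L, max_nm = 200L,
                            rule = c("approx", "strict"), tol_decades = 0.5) {
  rule <- match.arg(rule)
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("`records` must be a non-empty data frame")
  needed <- c("name", "length", "p_fs")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("`records` lacks column(s): ", paste(missing_cols, collapse = ", "))

  one <- function(i) {
    rec <- records[i, ]
    tryCatch({
      p_th <- percolation_threshold(rec$length, A_t, n_m)
      r_b <- biasing_ratio(p_th, rec$p_fs)
      nm <- min_nm(rec$length, A_t, rec$p_fs, max_nm = max_nm,
                   rule = rule, tol_decades = tol_decades)
      si <- sequence_identity(nm, rec$length)
      data.frame(name = rec$name, length = rec$length,
                 p_th = p_th, p_th_2sf = signif(p_th, 2),
                 p_fs = rec$p_fs,
                 r_b = r_b, r_b_exponent = order_of_magnitude(r_b),
                 n_min = nm, si = si, si_pct = as.integer(round(si)),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      stop("record '", rec$name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- do.call(rbind, lapply(seq_len(nrow(records)), one))
  for (extra in c("source", "known_discrepancy"))
    if (extra %in% names(records)) out[[extra]] <- records[[extra]]
  class(out) <- c("threshold_report", class(out))
  out
}

#' @export
print.threshold_report <- function(x, ...) {
  shown <- data.frame(
    name = x$name, L = x$length,
    P_th = format(x$p_th_2sf, scientific = FALSE),
    P_fs = format(x$p_fs, scientific = TRUE),
    R_b = paste0("10^", x$r_b_exponent),
    n_min = x$n_min, SI = paste0(x$si_pct, "%"),
    stringsAsFactors = FALSE)
  if (!is.null(x$known_discrepancy))
    shown$flag <- ifelse(x$known_discrepancy, "*", "")
  cat("Percolation threshold report (", nrow(x), " proteins)\n", sep = "")
  print(shown, row.names = FALSE, ...)
  if (!is.null(x$known_discrepancy) && any(x$known_discrepancy))
    cat("* row flagged as discrepant against its published source\n")
  invisible(x)
}

#' Read and write threshold tables
#'
#' `read_protein_table()` reads a TSV with header columns
#' `name, length, p_fs, source` (scientific notation accepted in `p_fs`).
#' `write_threshold_report()` writes a report as a TSV mirroring the
#' published table layout, optionally with a full-precision JSON companion.
#'
#' @param path input TSV path.
#' @return `read_protein_table()`: a data frame of protein records.
#' @export
read_protein_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "length", "p_fs")
  if (!all(needed %in% names(tab)))
    stop("expected columns name, length, p_fs in ", path)
  tab$p_fs <- as.numeric(tab$p_fs)
  tab
}

#' @rdname read_protein_table
#' @param report a `"threshold_report"` data frame.
#' @param tsv output TSV path.
#' @param json optional path for a JSON variant with full-precision fields.
#' @export
write_threshold_report <- function(report, tsv, json = NULL) {
  stopifnot(inherits(report, "threshold_report"))
  out <- data.frame(name = report$name, length = report$length,
                    p_th = report$p_th_2sf, p_fs = report$p_fs,
                    r_b = paste0("10^", report$r_b_exponent),
                    n_min = report$n_min, si = report$si_pct)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(as.data.frame(unclass(report))[, c(
      "name", "length", "p_th", "p_fs", "r_b", "r_b_exponent",
      "n_min", "si")], json, digits = NA, auto_unbox = TRUE)
  invisible(tsv)
}
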