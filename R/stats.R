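## Paired statistics: Wilcoxon signed-rank with exact tie-aware null
## distribution, Bonferroni-Holm adjustment, and the therapeutic-VTA
## duplication rule for the paresthesia comparison.

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Differences of zero are dropped ("wilcox" policy; "pratt" ranks them
#' first and then drops their contribution). Absolute differences are
#' ranked with midranks for ties. For effective n <= \code{exactMax} the
#' two-sided p-value comes from the exact null distribution of the
#' positive-rank sum (enumerated over all sign assignments by dynamic
#' programming, valid under ties); otherwise a normal approximation with
#' continuity and tie correction is used. The reported statistic is
#' W = min(W+, W-).
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exactMax largest effective n for the exact null.
#' @param zeroMethod "wilcox" (drop zeros) or "pratt".
#' @param exact force exact (TRUE) or approximate (FALSE) mode; NULL picks
#'   by \code{exactMax}.
#' @return list(statistic, p, n, wPlus, wMinus, method).
#' @export
wilcoxonSignedRank <- function(a, b, exactMax = 25L,
                               zeroMethod = c("wilcox", "pratt"),
                               exact = NULL) {
  zeroMethod <- match.arg(zeroMethod)
  stopifnot(length(a) == length(b), length(a) >= 1L)
  if (anyNA(a) || anyNA(b)) stop("paired values must not contain NA")
  d <- as.numeric(a) - as.numeric(b)
  if (all(d == 0)) {
    warning("all paired differences are zero")
    return(list(statistic = 0, p = 1, n = 0L, wPlus = 0, wMinus = 0,
                method = "degenerate"))
  }
  if (zeroMethod == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r0 <- rank(abs(d))          # zeros ranked, then their signs discarded
    r <- r0[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  wPlus <- sum(r[d > 0])
  wMinus <- sum(r[d < 0])
  useExact <- if (is.null(exact)) n <= exactMax else exact
  if (useExact) {
    # Exact null of W+ over the 2^n equiprobable sign assignments, via the
    # generating polynomial on doubled (integer) midranks.
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1L)
    f[1] <- 1
    for (rr in r2) {
      g <- f
      g[(rr + 1L):(tot + 1L)] <- g[(rr + 1L):(tot + 1L)] + f[1:(tot + 1L - rr)]
      f <- g
    }
    f <- f / sum(f)
    w2 <- as.integer(round(2 * wPlus))
    pLower <- sum(f[seq_len(w2 + 1L)])
    pUpper <- sum(f[(w2 + 1L):(tot + 1L)])
    p <- min(1, 2 * min(pLower, pUpper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (wPlus - mu - sign(wPlus - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = min(wPlus, wMinus), p = p, n = n,
       wPlus = wPlus, wMinus = wMinus, method = method)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "holm")}: sorted
#' ascending p-values are multiplied by (m - i + 1), made monotone
#' non-decreasing, capped at 1, and restored to input order.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
holmAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Pair therapeutic and paresthesia VTA overlaps by patient
#'
#' Builds the paired inputs for the paresthesia correspondence analysis:
#' one pair per paresthesia VTA, each pairing the patient's (single)
#' therapeutic VTA-sensory overlap with that paresthesia VTA's overlap.
#' A patient with three paresthesia VTAs thus contributes the therapeutic
#' value three times (the duplication rule enabling a pairwise test).
#'
#' @param records data.frame with at least columns patient_id, outcome
#'   ("therapeutic"/"paresthesia"), overlap_percent (typically already
#'   filtered to one atlas, method and the sensory region).
#' @return data.frame(patient_id, vta_id, therapeutic, paresthesia), one
#'   row per paresthesia VTA (zero rows if there are none).
#' @export
buildParesthesiaPairs <- function(records) {
  ther <- records[records$outcome == "therapeutic", , drop = FALSE]
  par <- records[records$outcome == "paresthesia", , drop = FALSE]
  if (!nrow(par))
    return(data.frame(patient_id = character(), vta_id = character(),
                      therapeutic = numeric(), paresthesia = numeric()))
  dupTher <- ther$patient_id[duplicated(ther$patient_id)]
  if (length(dupTher))
    stop("patients with multiple therapeutic records: ",
         paste(unique(dupTher), collapse = ", "))
  m <- match(par$patient_id, ther$patient_id)
  if (anyNA(m))
    stop("paresthesia record with no therapeutic record for patient: ",
         paste(unique(par$patient_id[is.na(m)]), collapse = ", "))
  data.frame(patient_id = par$patient_id,
             vta_id = if ("vta_id" %in% names(par)) par$vta_id else NA,
             therapeutic = ther$overlap_percent[m],
             paresthesia = par$overlap_percent,
             stringsAsFactors = FALSE)
}
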