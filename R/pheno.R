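## Fruit-tip phenotype coding and per-group summaries.

#' Classify the fruit tip from the distal-end angle
#'
#' A fruit is scored as pointed (1) iff the angle of the distal end lies
#' strictly between 0 and 180 degrees; flat or reflex angles (>= 180) score
#' 0. The boundary 180 is excluded by the strict inequality.
#'
#' @param theta tip angle(s) in degrees, in the open interval (0, 360).
#' @return Integer vector of tip codes (0/1); `NA` input gives `NA`.
#' @examples
#' classifyTip(c(90, 180, 270))
#' @export
classifyTip <- function(theta) {
  bad <- !is.na(theta) & (theta <= 0 | theta >= 360)
  if (any(bad))
    stop("theta must lie in (0, 360) degrees; offending value(s): ",
         paste(utils::head(theta[bad], 3), collapse = ", "), call. = FALSE)
  ifelse(is.na(theta), NA_integer_, as.integer(theta > 0 & theta < 180))
}

#' Per-group pointed-tip percentages
#'
#' Summarizes the binary tip code by taxonomic group. Where both `theta`
#' and `tip_code` are present the curated code is authoritative and checked
#' for consistency with the angle; where only `theta` is present the code is
#' derived with [classifyTip()]. Percentages are reported half-up to two
#' decimals and are invariant under record reordering.
#'
#' @param records data.frame with columns `group` and `tip_code` (and
#'   optionally `theta`).
#' @param groups optional group levels to report (defaults to the groups
#'   present); empty groups are flagged with `NA` percentages.
#' @return data.frame with columns `group`, `n`, `n_pointed`, `pointed_pct`.
#' @examples
#' rec <- data.frame(group = rep(c("BIG", "wild"), c(151, 55)),
#'                   tip_code = c(rep(1, 33), rep(0, 118), rep(0, 55)))
#' groupSummary(rec)
#' @export
groupSummary <- function(records, groups = NULL) {
  stopIfNot(all(c("group") %in% colnames(records)),
            "records must have a 'group' column")
  code <- if ("tip_code" %in% colnames(records)) records$tip_code else NULL
  if ("theta" %in% colnames(records)) {
    derived <- classifyTip(records$theta)
    if (is.null(code)) {
      code <- derived
    } else {
      both <- !is.na(code) & !is.na(derived)
      if (any(code[both] != derived[both]))
        warning(sum(code[both] != derived[both]),
                " record(s) with tip_code inconsistent with theta; ",
                "keeping the curated tip_code")
      code[is.na(code)] <- derived[is.na(code)]
    }
  }
  stopIfNot(!is.null(code), "records need a tip_code or theta column")
  stopIfNot(!anyNA(code), "every record needs a resolvable tip code")
  if (is.null(groups)) groups <- unique(records$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- records$group == g
    n <- sum(sel)
    np <- sum(code[sel] == 1L)
    data.frame(group = g, n = n, n_pointed = np,
               pointed_pct = if (n) roundHalfUp(100 * np / n, 2) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (any(out$n == 0))
    warning("empty group(s): ",
            paste(out$group[out$n == 0], collapse = ", "))
  out
}
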