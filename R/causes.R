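# Cause-of-death taxonomy for maternal mortality.
#
# The taxonomy is closed: exactly eight causes, with maternal hemorrhage
# split into its antepartum / intrapartum / postpartum components. Unknown
# cause labels are always an error, never silently dropped, because the
# impact model indexes cause-specific deaths by this fixed set.

#' Maternal cause-of-death taxonomy
#'
#' The fixed, closed set of eight causes of maternal death used throughout
#' the package: the three hemorrhage components (antepartum, intrapartum,
#' postpartum), hypertensive disorders, sepsis, abortion, other direct
#' causes and indirect causes.
#'
#' @return Character vector of the eight cause labels, in canonical order.
#' @export
#' @examples
#' maternal_causes()
maternal_causes <- function() {
  c("antepartum_hemorrhage", "intrapartum_hemorrhage",
    "postpartum_hemorrhage", "hypertensive_disorders", "sepsis",
    "abortion", "other_direct", "indirect")
}

# Fixed split of aggregate maternal hemorrhage into its three components,
# from the systematic analysis of global causes of maternal death:
# antepartum 24%, intrapartum 3%, postpartum 73%.
.hemorrhage_split <- c(antepartum_hemorrhage = 0.24,
                       intrapartum_hemorrhage = 0.03,
                       postpartum_hemorrhage = 0.73)

#' Decompose an aggregate hemorrhage share into its three components
#'
#' Splits an aggregate maternal-hemorrhage cause-of-death share into
#' antepartum, intrapartum and postpartum hemorrhage using the fixed
#' 24% / 3% / 73% decomposition. The three components always sum back to
#' the aggregate exactly.
#'
#' @param share Aggregate hemorrhage share, a fraction in \[0, 1\].
#' @return Named numeric vector of length 3 (`antepartum_hemorrhage`,
#'   `intrapartum_hemorrhage`, `postpartum_hemorrhage`).
#' @export
#' @examples
#' decompose_hemorrhage(0.27)
decompose_hemorrhage <- function(share) {
  if (!is.numeric(share) || length(share) != 1L || is.na(share) ||
      share < 0 || share > 1) {
    stop("aggregate hemorrhage share must be a single number in [0, 1], got ",
         deparse(share), call. = FALSE)
  }
  .hemorrhage_split * share
}

#' Cause-of-death profile
#'
#' Constructs and validates a cause-of-death profile: the fraction of
#' maternal deaths attributed to each of the eight causes in
#' [maternal_causes()]. Shares must each lie in \[0, 1\] and sum to 1.
#'
#' @param shares Named numeric vector with one entry per cause; names must
#'   be exactly the eight cause labels (any order).
#' @param tol Tolerance on the sum-to-one constraint (default `1e-9`).
#' @return Named numeric vector in canonical cause order, of class
#'   `"cause_profile"`.
#' @export
#' @examples
#' sh <- c(decompose_hemorrhage(0.27),
#'         hypertensive_disorders = 0.16, sepsis = 0.09, abortion = 0.08,
#'         other_direct = 0.15, indirect = 0.25)
#' cause_profile(sh)
cause_profile <- function(shares, tol = 1e-9) {
  causes <- maternal_causes()
  if (is.null(names(shares)) || !setequal(names(shares), causes) ||
      anyDuplicated(names(shares))) {
    extra <- setdiff(names(shares), causes)
    missing <- setdiff(causes, names(shares))
    stop("cause profile must name exactly the eight causes",
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  shares <- shares[causes]
  if (anyNA(shares) || any(shares < 0) || any(shares > 1)) {
    stop("cause shares must all lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(shares) - 1) > tol) {
    stop(sprintf("cause shares must sum to 1 (got %.12f)", sum(shares)),
         call. = FALSE)
  }
  structure(shares, class = "cause_profile")
}

#' @export
print.cause_profile <- function(x, ...) {
  cat("Cause-of-death profile (fractions of maternal deaths)\n")
  print(round(unclass(x), 4))
  invisible(x)
}
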