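#' Scenario-B weekday assignment
#'
#' Once-weekly surveillance (scenario B) is simulated by removing the
#' Monday or the Thursday surveillance cultures of each admission, the
#' weekday being drawn at random per admission and fixed for the whole stay.
#' The draw is a seeded hash of the admission id, not a sequential RNG, so
#' the assignment is deterministic, marginally uniform over the two
#' weekdays, and independent of table ordering.
#'
#' @param admission_id character vector of admission ids.
#' @param seed integer seed.
#' @return character vector in \{\code{"Monday"}, \code{"Thursday"}\}: the
#'   weekday whose surveillance cultures are dropped for each admission.
#' @export
assign_dropped_weekday <- function(admission_id, seed) {
  h <- hash31(as.character(admission_id), seed = seed)
  ifelse(h %% 2L == 0L, "Monday", "Thursday")
}

#' Build the culture subset for a surveillance scenario
#'
#' \describe{
#'   \item{A}{current practice: admission cultures plus twice-weekly
#'     (Monday and Thursday) surveillance — the identity filter.}
#'   \item{B}{once-weekly surveillance: surveillance cultures falling on the
#'     admission's dropped weekday (see [assign_dropped_weekday()]) are
#'     removed.}
#'   \item{C}{admission cultures only: all surveillance cultures removed.}
#' }
#' Admission cultures and clinical cultures are retained in every scenario;
#' retained records are never altered, so cultures(C) \eqn{\subseteq}
#' cultures(B) \eqn{\subseteq} cultures(A). Surveillance cultures on
#' weekdays other than Monday/Thursday (possible in real exports) are
#' retained in B: the removal rule is defined only on the two protocol days.
#'
#' @param cohort an [sdd_cohort()].
#' @param label scenario label, one of \code{"A"}, \code{"B"}, \code{"C"}.
#' @param seed integer seed for the scenario-B weekday draw (ignored by A
#'   and C).
#' @return the filtered culture data.frame. The attribute
#'   \code{"dropped_weekday"} (scenario B only) carries the per-admission
#'   assignment for audit.
#' @export
apply_scenario <- function(cohort, label, seed = 1L) {
  cul <- cohort$cultures
  if (!label %in% c("A", "B", "C"))
    stop("unknown scenario label: ", label, call. = FALSE)
  if (label == "A") return(cul)
  if (label == "C") return(cul[cul$category != "sdd_surveillance", ,
                               drop = FALSE])
  adm_ids <- cohort$admissions$admission_id
  dropped <- assign_dropped_weekday(adm_ids, seed)
  names(dropped) <- adm_ids
  wd <- wday_num(cul$collection_date)  # 1 = Monday, 4 = Thursday
  drop_wd <- ifelse(dropped[cul$admission_id] == "Monday", 1L, 4L)
  remove <- cul$category == "sdd_surveillance" & wd == drop_wd
  out <- cul[!remove, , drop = FALSE]
  attr(out, "dropped_weekday") <- data.frame(admission_id = adm_ids,
                                             dropped_weekday = unname(dropped),
                                             stringsAsFactors = FALSE)
  out
}
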