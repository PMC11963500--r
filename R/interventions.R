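# The fourteen-intervention registry.
#
# One periconceptual, three pregnancy and ten childbirth interventions,
# each acting on one or more causes of maternal death through an efficacy
# (proportional mortality reduction among those reached) and an affected
# fraction (share of cause-specific deaths the intervention can act on).
#
# The published efficacy / affected-fraction table lives in the LiST
# database and is not shipped here: the bundled config is a clearly
# labelled placeholder (see `interventions_placeholder.json`) and real
# analyses must supply their own values via `read_interventions()`.

.intervention_periods <- c("periconceptual", "pregnancy", "childbirth")

#' Maternal health intervention
#'
#' Constructs and validates one intervention: an identifier, a life-course
#' period, and for each target cause an efficacy and an affected fraction,
#' both fractions in \[0, 1\].
#'
#' @param id Short character identifier.
#' @param period One of `"periconceptual"`, `"pregnancy"`, `"childbirth"`.
#' @param targets Named list, one entry per target cause (names from
#'   [maternal_causes()]); each entry a list/vector with elements
#'   `efficacy` and `affected_fraction`.
#' @return An object of class `"intervention"`.
#' @export
#' @examples
#' intervention("uterotonics", "childbirth",
#'              list(postpartum_hemorrhage = list(efficacy = 0.8,
#'                                                affected_fraction = 1)))
intervention <- function(id, period, targets) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("intervention id must be a non-empty string", call. = FALSE)
  }
  if (!is.character(period) || length(period) != 1L ||
      !period %in% .intervention_periods) {
    stop(sprintf("intervention '%s': period must be one of %s", id,
                 paste(.intervention_periods, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.list(targets) || length(targets) == 0L || is.null(names(targets))) {
    stop(sprintf("intervention '%s': needs at least one named target cause", id),
         call. = FALSE)
  }
  unknown <- setdiff(names(targets), maternal_causes())
  if (length(unknown)) {
    stop(sprintf("intervention '%s': unknown target cause(s): %s", id,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  targets <- lapply(targets, function(t) {
    t <- as.list(t)
    eff <- as.numeric(t$efficacy)
    af <- as.numeric(t$affected_fraction)
    if (length(eff) != 1L || is.na(eff) || eff < 0 || eff > 1 ||
        length(af) != 1L || is.na(af) || af < 0 || af > 1) {
      stop(sprintf(
        "intervention '%s': efficacy and affected_fraction must be in [0, 1]",
        id), call. = FALSE)
    }
    list(efficacy = eff, affected_fraction = af)
  })
  structure(list(id = id, period = period, targets = targets),
            class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  cat(sprintf("Intervention '%s' (%s period)\n", x$id, x$period))
  for (cause in names(x$targets)) {
    t <- x$targets[[cause]]
    cat(sprintf("  %-24s efficacy %.2f  affected fraction %.2f\n",
                cause, t$efficacy, t$affected_fraction))
  }
  invisible(x)
}

#' Read an intervention registry from JSON
#'
#' Reads a registry config of the form
#' `[{"id", "period", "targets": [{"cause", "efficacy", "affected_fraction"}]}]`
#' and validates every entry.
#'
#' @param path Path to a JSON file.
#' @return List of [intervention()] objects, named by id.
#' @export
read_interventions <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(raw) || length(raw) == 0L) {
    stop("intervention config must be a non-empty JSON array", call. = FALSE)
  }
  regs <- lapply(seq_along(raw), function(i) {
    entry <- raw[[i]]
    if (is.null(entry$id) || is.null(entry$period) || is.null(entry$targets)) {
      stop(sprintf(
        "intervention config entry %d (id '%s'): needs id, period and targets",
        i, if (is.null(entry$id)) "?" else entry$id), call. = FALSE)
    }
    targets <- list()
    for (t in entry$targets) {
      if (is.null(t$cause)) {
        stop(sprintf("intervention config entry '%s': target without a cause",
                     entry$id), call. = FALSE)
      }
      targets[[t$cause]] <- list(efficacy = t$efficacy,
                                 affected_fraction = t$affected_fraction)
    }
    intervention(entry$id, entry$period, targets)
  })
  ids <- vapply(regs, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("intervention config has duplicate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(regs) <- ids
  regs
}

#' Write an intervention registry to JSON
#'
#' @param registry List of [intervention()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interventions <- function(registry, path) {
  out <- lapply(registry, function(iv) {
    list(id = iv$id, period = iv$period,
         targets = lapply(names(iv$targets), function(cause) {
           t <- iv$targets[[cause]]
           list(cause = cause, efficacy = t$efficacy,
                affected_fraction = t$affected_fraction)
         }))
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Default fourteen-intervention registry
#'
#' Returns the standard registry of fourteen maternal health interventions:
#' one periconceptual (safe abortion services), three pregnancy (tetanus
#' toxoid, micronutrient supplementation, hypertensive disorder case
#' management) and ten childbirth interventions (clean birth environment,
#' MgSO4 for eclampsia, antibiotics for PROM, antibiotics for maternal
#' sepsis, assisted vaginal delivery, uterotonics for postpartum
#' hemorrhage, manual removal of placenta, removal of retained products of
#' conception, cesarean delivery, blood transfusion).
#'
#' The efficacy and affected-fraction values bundled with the package are
#' PLACEHOLDERS (efficacies spread over 0.5-0.9, affected fractions 1.0,
#' plausible target-cause mappings): they reproduce the structure of the
#' LiST effectiveness database, not its values. Supply a real config via
#' `path` for substantive analyses.
#'
#' @param path Path to a registry JSON; defaults to the bundled
#'   placeholder config.
#' @return Named list of 14 [intervention()] objects (or however many the
#'   supplied config defines).
#' @export
#' @examples
#' reg <- default_intervention_registry()
#' length(reg)
#' table(vapply(reg, `[[`, "", "period"))
default_intervention_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "interventions_placeholder.json",
                        package = "mmrimpact", mustWork = TRUE)
  }
  read_interventions(path)
}
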