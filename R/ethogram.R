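# Behaviour catalog: codes, categories, recording mode, modifiers.
#
# The catalog tells the focal-log reader how to interpret each behaviour code
# (instantaneous event vs timed state, directional or not) and which codes
# count toward pair consort duration (PCD) and intensive body contact (IBC).

.behavior_categories <- c("mount", "intensive_body_contact", "contact_sitting",
                          "grooming", "other_affiliative", "proximity",
                          "separation")

#' Default behaviour catalog
#'
#' The built-in ethogram covers the behaviours that enter the consort
#' analysis: sexual mounting (instantaneous event with an optional
#' `pelvic_movement` modifier), the intensive-body-contact states (huddling
#' and embracing: full-surface, mutually maintained contact), contact
#' sitting, grooming (directional, both directions summed downstream),
#' cofeeding / travelling together / mutual following, an observer-recorded
#' 3 m proximity state, and an optional instantaneous separation marker that
#' truncates open states.
#'
#' Consort behaviour (the PCD set) comprises mounting, all body-contact
#' affiliative states, cofeeding, travelling together, mutual following and
#' 3 m proximity. IBC is restricted to huddling and embracing; contact
#' sitting and grooming are deliberately kept out of IBC.
#'
#' @return An object of class `ethogram`: a list with `behaviors` (data
#'   frame), `consort_behavior_codes`, `ibc_codes`, `proximity_radius_m`.
#' @export
default_ethogram <- function() {
  behaviors <- data.frame(
    code = c("mount", "embrace", "huddle", "contact_sit", "groom",
             "cofeed", "travel_together", "mutual_follow", "proximity_3m",
             "separation"),
    label = c("sexual mount (any posture)", "embrace", "huddle",
              "contact sitting", "social grooming", "cofeeding",
              "traveling together", "mutual following",
              "within 3 m spatial proximity", "pair separated beyond 3 m"),
    category = c("mount", "intensive_body_contact", "intensive_body_contact",
                 "contact_sitting", "grooming", "other_affiliative",
                 "other_affiliative", "other_affiliative", "proximity",
                 "separation"),
    mode = c("event", "state", "state", "state", "state", "state", "state",
             "state", "state", "event"),
    directional = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                    FALSE, FALSE),
    modifiers = c("pelvic_movement", "", "", "", "", "", "", "", "", ""),
    stringsAsFactors = FALSE
  )
  catalog <- list(
    behaviors = behaviors,
    consort_behavior_codes = c("mount", "embrace", "contact_sit", "huddle",
                               "groom", "cofeed", "travel_together",
                               "mutual_follow", "proximity_3m"),
    ibc_codes = c("huddle", "embrace"),
    proximity_radius_m = 3
  )
  class(catalog) <- "ethogram"
  validate_ethogram(catalog)
}

#' Validate a behaviour catalog
#'
#' Checks code uniqueness, category and mode vocabulary, the structural
#' invariants of the mount and IBC classes, and that `ibc_codes` is a subset
#' of the consort-behaviour set. Warns (but does not fail) when `ibc_codes`
#' departs from the huddle/embrace definition, since that changes the meaning
#' of the IBC variable.
#'
#' @param catalog An `ethogram` object or a bare list with the same fields.
#' @return The validated catalog, classed `ethogram`.
#' @export
validate_ethogram <- function(catalog) {
  b <- catalog$behaviors
  required <- c("code", "label", "category", "mode", "directional", "modifiers")
  if (!all(required %in% names(b))) {
    stop("behaviors table must have columns: ", paste(required, collapse = ", "))
  }
  dup <- unique(b$code[duplicated(b$code)])
  if (length(dup) > 0L) {
    stop("duplicate behavior code(s): ", paste(dup, collapse = ", "))
  }
  bad_cat <- setdiff(b$category, .behavior_categories)
  if (length(bad_cat) > 0L) {
    stop("unknown behavior category: ", paste(bad_cat, collapse = ", "))
  }
  bad_mode <- setdiff(b$mode, c("event", "state"))
  if (length(bad_mode) > 0L) {
    stop("unknown recording mode: ", paste(bad_mode, collapse = ", "))
  }
  # mounting is an instantaneous, directional event
  m <- b[b$category == "mount", , drop = FALSE]
  if (nrow(m) > 0L && (any(m$mode != "event") || any(!m$directional))) {
    stop("mount behaviors must be mode = 'event' and directional")
  }
  st_cat <- c("intensive_body_contact", "contact_sitting", "grooming",
              "proximity")
  st <- b[b$category %in% st_cat, , drop = FALSE]
  if (any(st$mode != "state")) {
    stop("body-contact, grooming and proximity behaviors must be states")
  }
  if (any(b$category == "grooming" & !b$directional)) {
    stop("grooming must be directional (actor grooms receiver)")
  }
  if (any(b$category == "intensive_body_contact" & b$directional)) {
    stop("intensive body contact is mutual, not directional")
  }
  undef <- setdiff(c(catalog$consort_behavior_codes, catalog$ibc_codes), b$code)
  if (length(undef) > 0L) {
    stop("referenced behavior code(s) not defined: ",
         paste(undef, collapse = ", "))
  }
  missing_ibc <- setdiff(catalog$ibc_codes, catalog$consort_behavior_codes)
  if (length(missing_ibc) > 0L) {
    stop("ibc code(s) missing from the consort-behavior set: ",
         paste(missing_ibc, collapse = ", "))
  }
  if (!is.numeric(catalog$proximity_radius_m) ||
      catalog$proximity_radius_m <= 0) {
    stop("proximity_radius_m must be a positive length in meters")
  }
  ibc_cat <- b$category[match(catalog$ibc_codes, b$code)]
  if (any(ibc_cat != "intensive_body_contact")) {
    warning("ibc_codes include behaviors outside the intensive_body_contact ",
            "category (", paste(catalog$ibc_codes[ibc_cat !=
              "intensive_body_contact"], collapse = ", "),
            "); this departs from the huddle/embrace IBC definition",
            call. = FALSE)
  }
  class(catalog) <- "ethogram"
  catalog
}

#' Read a behaviour catalog from a YAML document
#'
#' @param source Path to a YAML file with fields `behaviors` (list of
#'   records with `code`, `label`, `category`, `mode`, `directional`,
#'   `modifiers`), `consort_behavior_codes`, `ibc_codes`,
#'   `proximity_radius_m`. Missing top-level fields fall back to the
#'   defaults of [default_ethogram()].
#' @return A validated `ethogram` object.
#' @export
load_ethogram <- function(source) {
  doc <- yaml::read_yaml(source)
  if (is.null(doc$behaviors)) stop("ethogram document has no 'behaviors' field")
  rows <- lapply(doc$behaviors, function(x) {
    if (is.null(x$code)) stop("behavior entry without a code")
    data.frame(code = x$code,
               label = x$label %||% x$code,
               category = x$category %||% stop("behavior '", x$code,
                                               "' has no category"),
               mode = x$mode %||% "state",
               directional = isTRUE(x$directional),
               modifiers = paste(x$modifiers %||% character(0), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  defaults <- default_ethogram()
  catalog <- list(
    behaviors = do.call(rbind, rows),
    consort_behavior_codes = unlist(doc$consort_behavior_codes) %||%
      defaults$consort_behavior_codes,
    ibc_codes = unlist(doc$ibc_codes) %||% defaults$ibc_codes,
    proximity_radius_m = doc$proximity_radius_m %||%
      defaults$proximity_radius_m
  )
  validate_ethogram(catalog)
}

#' Write a behaviour catalog to YAML
#'
#' `load_ethogram(write_ethogram(catalog, path))` reproduces the catalog
#' field-for-field.
#'
#' @param catalog An `ethogram` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ethogram <- function(catalog, path) {
  catalog <- validate_ethogram(catalog)
  b <- catalog$behaviors
  doc <- list(
    behaviors = lapply(seq_len(nrow(b)), function(i) {
      mods <- strsplit(b$modifiers[i], ";", fixed = TRUE)[[1L]]
      list(code = b$code[i], label = b$label[i], category = b$category[i],
           mode = b$mode[i], directional = b$directional[i],
           modifiers = as.list(mods))
    }),
    consort_behavior_codes = as.list(catalog$consort_behavior_codes),
    ibc_codes = as.list(catalog$ibc_codes),
    proximity_radius_m = catalog$proximity_radius_m
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

# Lookup helpers used by the readers and aggregators.
behavior_mode <- function(catalog, code) {
  catalog$behaviors$mode[match(code, catalog$behaviors$code)]
}
behavior_directional <- function(catalog, code) {
  catalog$behaviors$directional[match(code, catalog$behaviors$code)]
}
allowed_modifiers <- function(catalog, code) {
  strsplit(catalog$behaviors$modifiers[match(code, catalog$behaviors$code)],
           ";", fixed = TRUE)[[1L]]
}
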