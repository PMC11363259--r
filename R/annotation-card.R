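#' The standardized rTLH annotation card
#'
#' An annotation card is the ordered list of functional surgical steps used to
#' segment a robot-assisted total laparoscopic hysterectomy (rTLH). Each step
#' has a canonical name, a laterality (`"none"` for midline steps, `"paired"`
#' for steps performed once per side), an optional flag, and free-text start
#' and stop actions that tell the annotator when the step begins and ends.
#'
#' @param steps A data frame with columns `name`, `laterality`, `optional`,
#'   `start_action`, `stop_action` and `card_index`.
#' @return A tibble of class `opi_card`, ordered by `card_index`.
#' @export
annotation_card <- function(steps) {
  steps <- tibble::as_tibble(steps)
  required <- c("name", "laterality", "optional", "start_action",
                "stop_action", "card_index")
  missing <- setdiff(required, names(steps))
  if (length(missing) > 0) {
    stop("annotation card is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  steps$name <- as.character(steps$name)
  steps$laterality <- as.character(steps$laterality)
  steps$optional <- as.logical(steps$optional)
  steps$card_index <- as.integer(steps$card_index)
  if (anyDuplicated(steps$name)) {
    stop("duplicate step name(s) in annotation card: ",
         paste(unique(steps$name[duplicated(steps$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(steps$laterality %in% c("none", "paired"))) {
    stop("laterality must be 'none' or 'paired'", call. = FALSE)
  }
  if (anyNA(steps$optional)) {
    stop("optional flag must be TRUE/FALSE for every step", call. = FALSE)
  }
  steps <- steps[order(steps$card_index), , drop = FALSE]
  if (!identical(steps$card_index, seq_len(nrow(steps)))) {
    stop("card_index values must be unique and contiguous from 1",
         call. = FALSE)
  }
  structure(steps, class = c("opi_card", class(steps)))
}

#' Default rTLH annotation card
#'
#' The built-in card holds the 11 functional steps of a standard rTLH:
#' four optional preparatory steps (adhesiolysis and adnexal dissections),
#' then the mandatory sequence from division of the round ligament through
#' vaginal cuff closure. Six steps are paired (performed on the left and the
#' right side).
#'
#' @return An `opi_card` with 11 steps.
#' @export
default_card <- function() {
  annotation_card(tibble::tibble(
    name = c(
      "Mobilize Colon/Removal of Adhesions",
      "Dissection of Fallopian Tube",
      "Dissection of IP Ligament",
      "Dissection of Utero-Ovarian Ligament",
      "Division of the Round Ligament",
      "Division of the Broad Ligament",
      "Bladder Flap Creation",
      "Division of Uterine Vessels",
      "Colpotomy",
      "Removal of the Uterus",
      "Vaginal Cuff Closure"
    ),
    laterality = c("none", "paired", "paired", "paired", "paired", "paired",
                   "none", "paired", "none", "none", "none"),
    optional = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE),
    start_action = c(
      "First grasp of colon or adhesion tissue",
      "First grasp of the fallopian tube",
      "First grasp of the infundibulopelvic ligament",
      "First grasp of the utero-ovarian ligament",
      "Instrument contacts the round ligament",
      "Instrument contacts the broad ligament",
      "First incision of the vesicouterine peritoneum",
      "Instrument contacts the uterine vessels",
      "First incision of the vaginal wall",
      "First traction on the detached uterus",
      "Needle clamped in the needle holder"
    ),
    stop_action = c(
      "Colon mobile / adhesions released",
      "Tube fully detached",
      "Ligament fully divided",
      "Ligament fully divided",
      "Ligament fully divided",
      "Broad ligament opened to planned extent",
      "Bladder reflected off the cervix",
      "Vessels sealed and divided",
      "Vagina opened circumferentially",
      "Uterus out of the operative field",
      "Barbed thread cut after complete closure"
    ),
    card_index = 1:11
  ))
}

#' Read an annotation card from JSON or YAML
#'
#' The file holds a list of step records with keys `name`, `laterality`
#' (`"none"` or `"paired"`), `optional`, `start_action` and `stop_action`;
#' card order follows file order unless `card_index` is given explicitly.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `opi_card`.
#' @export
read_card <- function(path) {
  if (!file.exists(path)) {
    stop("annotation card file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  if (is.null(raw) || length(raw) == 0) {
    stop("annotation card file is empty: ", path, call. = FALSE)
  }
  steps <- lapply(seq_along(raw), function(i) {
    s <- raw[[i]]
    for (key in c("name", "laterality", "optional", "start_action",
                  "stop_action")) {
      if (is.null(s[[key]])) {
        stop("card entry ", i, " is missing required field '", key, "'",
             call. = FALSE)
      }
    }
    tibble::tibble(
      name = s$name, laterality = s$laterality, optional = s$optional,
      start_action = s$start_action, stop_action = s$stop_action,
      card_index = if (is.null(s$card_index)) i else as.integer(s$card_index)
    )
  })
  annotation_card(dplyr::bind_rows(steps))
}

#' Write an annotation card to JSON or YAML
#'
#' @param card An `opi_card`.
#' @param path Destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_card <- function(card, path) {
  stopifnot(inherits(card, "opi_card"))
  recs <- lapply(seq_len(nrow(card)), function(i) {
    list(name = card$name[i], laterality = card$laterality[i],
         optional = card$optional[i], start_action = card$start_action[i],
         stop_action = card$stop_action[i],
         card_index = card$card_index[i])
  })
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(recs, path)
  } else {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.opi_card <- function(x, ...) {
  cat("rTLH annotation card:", nrow(x), "steps (",
      sum(x$laterality == "paired"), "paired,",
      sum(x$optional), "optional )\n")
  NextMethod()
}

# ---- step labels -----------------------------------------------------------

#' Compose a step label from a name and side
#'
#' Paired steps carry a side (`"left"` or `"right"`) rendered as
#' `"Name (side)"`; midline steps use the bare name. Labels are the state
#' symbols used in step sequences and transition matrices.
#'
#' @param name Canonical step name(s).
#' @param side `"none"`, `""`, `"left"` or `"right"` (recycled).
#' @return Character vector of labels.
#' @export
step_label <- function(name, side = "none") {
  side <- ifelse(is.na(side) | side == "", "none", side)
  ifelse(side == "none", name, paste0(name, " (", side, ")"))
}

#' Split labels back into name and side
#'
#' @param label Character vector of labels as produced by [step_label()].
#' @return A tibble with columns `name` and `side`.
#' @export
split_label <- function(label) {
  m <- regmatches(label, regexec("^(.*) \\((left|right)\\)$", label))
  name <- vapply(seq_along(label), function(i) {
    if (length(m[[i]]) == 3) m[[i]][2] else label[i]
  }, character(1))
  side <- vapply(seq_along(label), function(i) {
    if (length(m[[i]]) == 3) m[[i]][3] else "none"
  }, character(1))
  tibble::tibble(name = name, side = side)
}

#' All valid labels of a card
#'
#' Expands paired steps into their right and left variants (right first,
#' the convention used for state ordering) and keeps midline steps as-is,
#' in card order.
#'
#' @param card An `opi_card`.
#' @return Character vector of labels.
#' @export
card_labels <- function(card) {
  stopifnot(inherits(card, "opi_card"))
  unlist(lapply(seq_len(nrow(card)), function(i) {
    if (card$laterality[i] == "paired") {
      step_label(card$name[i], c("right", "left"))
    } else {
      card$name[i]
    }
  }))
}

#' Validate a (name, side) pair against a card
#'
#' @param name,side Vectors of step names and sides.
#' @param card An `opi_card`.
#' @return Invisibly `TRUE`; errors on the first violation.
#' @keywords internal
check_labels <- function(name, side, card) {
  side <- ifelse(is.na(side) | side == "", "none", side)
  unknown <- setdiff(unique(name), card$name)
  if (length(unknown) > 0) {
    stop("unknown step name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lat <- card$laterality[match(name, card$name)]
  bad_side <- !(side %in% c("none", "left", "right"))
  if (any(bad_side)) {
    stop("invalid side value(s): ",
         paste(unique(side[bad_side]), collapse = ", "), call. = FALSE)
  }
  mismatch <- (lat == "paired") != (side != "none")
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    stop("step '", name[i], "' is ", lat[i], " but side is '", side[i], "'",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' The START pseudo-state label
#' @return The string used for the start pseudo-state.
#' @export
start_state <- function() "START"
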