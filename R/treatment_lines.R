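# Ordinal treatment-prescription (line-of-therapy) assignment and the
# regimen taxonomy used for the per-ordinal summary table. Claims carry no
# stated treatment intent, so line advancement is inferred from the episode
# timeline: a grace window collects the classes that make up a regimen, and
# a new line opens on a class switch/addition after the grace window or on
# any restart after all of the current regimen's supply has lapsed.

#' Assign ordinal treatment prescriptions from class-level episodes
#'
#' Line 1 starts at the patient's first treatment episode (or at a supplied
#' index date). A line's class set is every drug class with an episode
#' starting within `grace_days` of the line start. A new line opens at the
#' first episode start that either (a) introduces a class outside the
#' current line's class set after the grace window, or (b) occurs after all
#' of the current line's episodes have exhausted their supply. At most
#' `max_lines` lines are emitted per patient; a line ends the day before
#' the next line starts (the last line ends at its last supply-end date).
#'
#' @param episodes Class-level episode tibble from [chain_episodes()].
#' @param grace_days Window after line start during which additional classes
#'   join the same regimen (default 30).
#' @param max_lines Maximum number of ordinals per patient (default 4).
#' @param index_dates Optional named Date vector (patient id to index date)
#'   anchoring line 1; defaults to each patient's first episode start.
#' @return Tibble with `patient_id`, `ordinal`, `start_date`, `end_date`,
#'   `classes` (sorted, `+`-separated), `has_acute`, `has_preventive`.
#' @export
assign_lines <- function(episodes, grace_days = 30, max_lines = 4,
                         index_dates = NULL) {
  empty <- tibble(patient_id = character(), ordinal = integer(),
                  start_date = as.Date(character()),
                  end_date = as.Date(character()), classes = character(),
                  has_acute = logical(), has_preventive = logical())
  if (nrow(episodes) == 0) return(empty)
  eps <- arrange(episodes, .data$patient_id, .data$start_date, .data$key)
  pieces <- lapply(split(eps, eps$patient_id), function(d) {
    first_start <- d$start_date[1]
    anchor <- index_dates[d$patient_id[1]]
    line_start <- if (!is.null(index_dates) && !is.na(anchor)) {
      min(as.Date(anchor), first_start)
    } else {
      first_start
    }
    lines <- list()
    class_set <- character()
    line_max_end <- as.Date(-Inf, origin = "1970-01-01")
    for (i in seq_len(nrow(d))) {
      st <- d$start_date[i]
      cl <- d$drug_class[i]
      joins <- st <= line_start + grace_days ||
        (st <= line_max_end && cl %in% class_set)
      if (!joins) {
        lines[[length(lines) + 1]] <- list(
          start = line_start, end = st - 1, classes = class_set)
        if (length(lines) >= max_lines) {
          class_set <- NULL
          break
        }
        line_start <- st
        class_set <- character()
        line_max_end <- as.Date(-Inf, origin = "1970-01-01")
      }
      class_set <- union(class_set, cl)
      line_max_end <- max(line_max_end, d$supply_end_date[i])
    }
    if (!is.null(class_set) && length(class_set) > 0) {
      lines[[length(lines) + 1]] <- list(
        start = line_start, end = line_max_end, classes = class_set)
    }
    tibble(
      patient_id = d$patient_id[1],
      ordinal = seq_along(lines),
      start_date = as.Date(vapply(lines, function(l) as.numeric(l$start),
                                  numeric(1)), origin = "1970-01-01"),
      end_date = as.Date(vapply(lines, function(l) as.numeric(l$end),
                                numeric(1)), origin = "1970-01-01"),
      classes = vapply(lines, function(l)
        paste(sort(l$classes), collapse = "+"), character(1)))
  })
  out <- bind_rows(pieces)
  out %>%
    mutate(
      has_acute = vapply(strsplit(.data$classes, "+", fixed = TRUE),
                         function(x) any(x %in% ACUTE_CLASSES), logical(1)),
      has_preventive = vapply(strsplit(.data$classes, "+", fixed = TRUE),
                              function(x) any(x %in% PREVENTIVE_CLASSES),
                              logical(1))) %>%
    arrange(.data$patient_id, .data$ordinal)
}

#' Classify a regimen into taxonomy cells
#'
#' Emits one cell per drug class present in the regimen, so that per-class
#' cell counts sum to the class total. For each class the cell is: `only`
#' when the class is alone; `plus_preventive` (acute rows) or
#' `plus_other_preventive` (preventive rows) when any (other) preventive
#' class is co-prescribed; the specific named pairing when exactly one other
#' class accompanies it; and the residual `plus_others` for remaining
#' multi-class combinations. Pair cells are mirrored: the count of
#' `triptan_plus_acetaminophen_nsaid` always equals
#' `acetaminophen_nsaid_plus_triptan`.
#'
#' @param classes Character vector of drug classes in one regimen.
#' @return Character vector of taxonomy cell labels, one per class present.
#' @export
classify_regimen <- function(classes) {
  classes <- unique(classes)
  vapply(classes, function(cl) {
    comp <- setdiff(classes, cl)
    other_prev <- comp[comp %in% PREVENTIVE_CLASSES]
    if (length(comp) == 0) {
      paste0(cl, "_only")
    } else if (length(other_prev) > 0) {
      if (cl %in% ACUTE_CLASSES) paste0(cl, "_plus_preventive")
      else paste0(cl, "_plus_other_preventive")
    } else if (length(comp) == 1) {
      paste0(cl, "_plus_", comp)
    } else {
      paste0(cl, "_plus_others")
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Per-ordinal treatment-prescription summary table
#'
#' Counts and percentages per taxonomy cell and per ordinal. The
#' denominator at ordinal k is the number of patients with a k-th line;
#' percentages are rounded half-up to one decimal. Ordinals with no
#' patients are omitted.
#'
#' @param lines Output of [assign_lines()].
#' @return Tibble with `ordinal`, `label`, `n`, `pct`. Labels cover
#'   `n_patients`, `any_acute`, `any_preventive`, each drug-class total and
#'   each taxonomy cell present.
#' @export
line_summary_table <- function(lines) {
  if (nrow(lines) == 0) {
    return(tibble(ordinal = integer(), label = character(), n = integer(),
                  pct = numeric()))
  }
  split_classes <- strsplit(lines$classes, "+", fixed = TRUE)
  cells <- lapply(split_classes, classify_regimen)
  pieces <- lapply(sort(unique(lines$ordinal)), function(k) {
    sel <- lines$ordinal == k
    den <- sum(sel)
    cls_k <- split_classes[sel]
    cells_k <- unlist(cells[sel])
    class_counts <- vapply(c(ACUTE_CLASSES, PREVENTIVE_CLASSES),
                           function(cl) sum(vapply(cls_k, function(x)
                             cl %in% x, logical(1))), integer(1))
    cell_tab <- table(cells_k)
    lab <- c("n_patients", "any_acute", "any_preventive",
             names(class_counts), names(cell_tab))
    n <- c(den, sum(lines$has_acute[sel]), sum(lines$has_preventive[sel]),
           unname(class_counts), as.integer(cell_tab))
    tibble(ordinal = k, label = lab, n = n,
           pct = pct(n, den))
  })
  bind_rows(pieces)
}
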