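#' Emergence-trial datasets
#'
#' A `trial_dataset` is a data frame with one row per experimental trial of
#' one individual cricket, carrying the columns
#' \describe{
#'   \item{individual_id}{character, opaque identifier}
#'   \item{group}{factor with levels `virus_free`, `infected`}
#'   \item{sex}{factor with levels `male`, `female`; may be `NA` (rejected
#'     only by operations that disaggregate by sex)}
#'   \item{trial_index}{integer >= 1, the individual's cumulative experience
#'     count (1st, 2nd, ... trial), not a calendar day}
#'   \item{emerged}{logical, whether the animal fully left the tube within
#'     the observation window}
#'   \item{latency_s}{numeric seconds, present iff `emerged`; valid values
#'     lie in \[1, 599\] for the standard 10-minute window}
#' }
#'
#' @param records data frame with the columns above (`latency_s` must be
#'   `NA` where `emerged` is `FALSE`).
#' @return An object of class `trial_dataset` (a data frame).
#' @seealso [read_trials()], [write_trials()], [validate_dataset()]
#' @export
trial_dataset <- function(records) {
  required <- c("individual_id", "group", "sex", "trial_index", "emerged",
                "latency_s")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ds <- data.frame(
    individual_id = as.character(records$individual_id),
    group  = factor(as.character(records$group), levels = group_levels()),
    sex    = factor(as.character(records$sex), levels = sex_levels()),
    trial_index = as.integer(records$trial_index),
    emerged = as.logical(records$emerged),
    latency_s = as.numeric(records$latency_s),
    stringsAsFactors = FALSE
  )
  class(ds) <- c("trial_dataset", "data.frame")
  ds
}

group_levels <- function() c("virus_free", "infected")
sex_levels <- function() c("male", "female")

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %d records, %d individuals (%s)\n",
              nrow(x), length(unique(x$individual_id)),
              paste(sprintf("%s: %d", group_levels(),
                            tabulate(match(x$group[!duplicated(x$individual_id)],
                                           group_levels()), 2L)),
                    collapse = ", ")))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Derived per-individual index of a dataset
#'
#' @param ds a [trial_dataset()].
#' @return Data frame with one row per individual: `individual_id`, `group`,
#'   `sex`, `n_trials`, `n_emerged`. Order follows first appearance in `ds`.
#' @export
individuals <- function(ds) {
  ids <- unique(ds$individual_id)
  first <- match(ids, ds$individual_id)
  data.frame(
    individual_id = ids,
    group = ds$group[first],
    sex = ds$sex[first],
    n_trials = as.integer(table(factor(ds$individual_id, levels = ids))),
    n_emerged = as.integer(rowsum(as.numeric(ds$emerged),
                                  factor(ds$individual_id, levels = ids))),
    stringsAsFactors = FALSE
  )
}

#' Table dialect for reading trial files
#'
#' The deposited archive's column names are not fixed by this package, so the
#' reader takes a dialect object mapping file headers and value encodings to
#' the canonical schema.
#'
#' @param columns named list mapping canonical names (`individual_id`,
#'   `group`, `sex`, `trial_index`, `emerged`, `latency_s`) to the file's
#'   header names.
#' @param group_labels named character vector mapping file values to
#'   canonical group levels, e.g. `c(control = "virus_free")`.
#' @param sex_labels named character vector mapping file values to canonical
#'   sex levels.
#' @param emerged_true,emerged_false file encodings of the emerged flag.
#' @param na_strings strings read as missing.
#' @param sep field separator.
#' @return A `trial_dialect` list.
#' @export
trial_dialect <- function(columns = list(),
                          group_labels = c(virus_free = "virus_free",
                                           infected = "infected"),
                          sex_labels = c(male = "male", female = "female"),
                          emerged_true = c("1", "TRUE", "true", "yes"),
                          emerged_false = c("0", "FALSE", "false", "no"),
                          na_strings = c("", "NA"),
                          sep = ",") {
  canonical <- c("individual_id", "group", "sex", "trial_index", "emerged",
                 "latency_s")
  cols <- stats::setNames(as.list(canonical), canonical)
  for (nm in names(columns)) {
    if (!nm %in% canonical) stop("unknown canonical column: ", nm, call. = FALSE)
    cols[[nm]] <- columns[[nm]]
  }
  structure(list(columns = cols, group_labels = group_labels,
                 sex_labels = sex_labels, emerged_true = emerged_true,
                 emerged_false = emerged_false, na_strings = na_strings,
                 sep = sep),
            class = "trial_dialect")
}

#' Read a dialect description from a YAML config file
#'
#' @param path YAML file; any subset of the [trial_dialect()] arguments may
#'   appear as top-level keys.
#' @return A `trial_dialect`.
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg),
                        names(formals(trial_dialect)))]
  for (nm in c("group_labels", "sex_labels")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  do.call(trial_dialect, args)
}

#' Read emergence trials from a delimited text file
#'
#' @param path CSV file with a header row.
#' @param dialect a [trial_dialect()] describing column names and value
#'   encodings.
#' @return A validated-for-structure [trial_dataset()] (content rules are
#'   checked separately by [validate_dataset()]). Row order is preserved.
#' @export
read_trials <- function(path, dialect = trial_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = dialect$na_strings,
                           stringsAsFactors = FALSE)
  cols <- dialect$columns
  missing_cols <- vapply(cols, function(h) !h %in% names(raw), logical(1))
  if (any(missing_cols)) {
    stop("missing required column(s): ",
         paste(unlist(cols[missing_cols]), collapse = ", "), call. = FALSE)
  }

  parse_enum <- function(vals, map, what) {
    out <- rep(NA_character_, length(vals))
    known <- vals %in% names(map)
    out[known] <- unname(map[vals[known]])
    bad <- which(!known & !is.na(vals))
    if (length(bad) > 0L) {
      stop(sprintf("row %d: unparseable %s value '%s'", bad[1L], what,
                   vals[bad[1L]]), call. = FALSE)
    }
    out
  }
  parse_num <- function(vals, what, integer = FALSE) {
    out <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(out) & !is.na(vals))
    if (length(bad) > 0L) {
      stop(sprintf("row %d: unparseable %s value '%s'", bad[1L], what,
                   vals[bad[1L]]), call. = FALSE)
    }
    if (integer) {
      frac <- which(!is.na(out) & out != round(out))
      if (length(frac) > 0L) {
        stop(sprintf("row %d: non-integer %s value '%s'", frac[1L], what,
                     vals[frac[1L]]), call. = FALSE)
      }
    }
    out
  }
  emg_raw <- raw[[cols$emerged]]
  emerged <- rep(NA, length(emg_raw))
  emerged[emg_raw %in% dialect$emerged_true] <- TRUE
  emerged[emg_raw %in% dialect$emerged_false] <- FALSE
  bad <- which(is.na(emerged) & !is.na(emg_raw))
  if (length(bad) > 0L) {
    stop(sprintf("row %d: unparseable emerged value '%s'", bad[1L],
                 emg_raw[bad[1L]]), call. = FALSE)
  }

  trial_dataset(data.frame(
    individual_id = raw[[cols$individual_id]],
    group = parse_enum(raw[[cols$group]], dialect$group_labels, "group"),
    sex = parse_enum(raw[[cols$sex]], dialect$sex_labels, "sex"),
    trial_index = parse_num(raw[[cols$trial_index]], "trial_index",
                            integer = TRUE),
    emerged = emerged,
    latency_s = parse_num(raw[[cols$latency_s]], "latency"),
    stringsAsFactors = FALSE
  ))
}

#' Write emergence trials to a CSV file
#'
#' Writing then reading with the default dialect reproduces the dataset
#' record-for-record.
#'
#' @param ds a [trial_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(ds, path) {
  out <- as.data.frame(ds)
  out$emerged <- as.integer(out$emerged)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Validate an emergence-trial dataset
#'
#' Checks every content invariant and reports all violations (not just the
#' first). Rules:
#' \describe{
#'   \item{latency_bounds}{`emerged` implies `latency_s` in \[1,
#'     `observation_limit_s` - 1\]}
#'   \item{latency_missing}{`emerged` implies `latency_s` present}
#'   \item{latency_spurious}{not `emerged` implies `latency_s` absent}
#'   \item{trial_index_positive}{`trial_index >= 1`}
#'   \item{trial_index_duplicate}{trial indices distinct within individual}
#'   \item{inconsistent_group}{one group per individual}
#'   \item{inconsistent_sex}{one sex per individual}
#'   \item{missing_field}{`individual_id`, `group`, `trial_index` or
#'     `emerged` missing}
#' }
#'
#' @param ds a [trial_dataset()].
#' @param observation_limit_s observation window in seconds (default 600,
#'   the study's 10-minute limit).
#' @return Data frame of violations with columns `rule`, `row`,
#'   `individual_id`, `message`; zero rows iff the dataset is valid.
#' @export
validate_dataset <- function(ds, observation_limit_s = 600) {
  v <- list()
  flag <- function(rule, rows, msg) {
    if (length(rows) == 0L) return()
    v[[length(v) + 1L]] <<- data.frame(
      rule = rule, row = rows,
      individual_id = ds$individual_id[rows],
      message = msg, stringsAsFactors = FALSE)
  }

  flag("missing_field",
       which(is.na(ds$individual_id) | is.na(ds$group) |
               is.na(ds$trial_index) | is.na(ds$emerged)),
       "individual_id, group, trial_index and emerged are required")
  flag("trial_index_positive", which(!is.na(ds$trial_index) & ds$trial_index < 1L),
       "trial_index must be >= 1")
  emg <- !is.na(ds$emerged) & ds$emerged
  flag("latency_missing", which(emg & is.na(ds$latency_s)),
       "emerged records must carry a latency")
  flag("latency_bounds",
       which(emg & !is.na(ds$latency_s) &
               (ds$latency_s < 1 | ds$latency_s > observation_limit_s - 1)),
       sprintf("latency out of bounds [1, %d]", observation_limit_s - 1L))
  flag("latency_spurious", which(!is.na(ds$emerged) & !ds$emerged &
                                   !is.na(ds$latency_s)),
       "non-emerged records must not carry a latency")

  by_id <- split(seq_len(nrow(ds)), ds$individual_id)
  for (rows in by_id) {
    dup <- rows[duplicated(ds$trial_index[rows])]
    flag("trial_index_duplicate", dup,
         "duplicate trial_index within individual")
    g <- ds$group[rows]
    if (length(unique(g[!is.na(g)])) > 1L) {
      flag("inconsistent_group", rows[-1L],
           "individual listed under more than one group")
    }
    s <- ds$sex[rows]
    if (length(unique(s[!is.na(s)])) > 1L) {
      flag("inconsistent_sex", rows[-1L],
           "individual listed under more than one sex")
    }
  }
  out <- if (length(v) == 0L) {
    data.frame(rule = character(), row = integer(),
               individual_id = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
  out[order(out$row), , drop = FALSE]
}
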