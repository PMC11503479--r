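#' Occasion scheme for a cohort's first year
#'
#' Defines the cohort-relative date windows that discretize the first year
#' from ringing into five occasions plus a terminal "ever after" occasion:
#' occasion 1 is the natal breeding season (ringing to 15 August), occasions
#' 2–3 together form autumn (16 August – 31 October), occasions 4–5 winter
#' (1 November – 31 March of the following calendar year), and occasion 6
#' collects any later resighting. Occasions 2/3 split on 1 October and 4/5 on
#' 1 January; all boundaries are configurable.
#'
#' @param cohort_year Integer ringing (fledging) year.
#' @param starts Named character vector of month-day (`"mm-dd"`) window
#'   starts for occasions 1–6; occasions 5 and 6 fall in `cohort_year + 1`.
#' @return An `occasion_scheme`: list with `cohort_year`, `starts` (Date
#'   vector of length 6) and `seasons` (season index of occasions 2–5;
#'   1 = autumn, 2 = winter).
#' @export
default_scheme <- function(cohort_year,
                           starts = c(o1 = "04-01", o2 = "08-16", o3 = "10-01",
                                      o4 = "11-01", o5 = "01-01", o6 = "04-01")) {
  stopifnot(length(starts) == 6L)
  yr <- c(rep(cohort_year, 4L), cohort_year + 1L, cohort_year + 1L)
  d <- as.Date(paste0(yr, "-", starts))
  if (any(diff(d) <= 0)) stopf("occasion windows must be ordered and non-overlapping")
  structure(list(cohort_year = as.integer(cohort_year), starts = d,
                 seasons = c(1L, 1L, 2L, 2L)),
            class = "occasion_scheme")
}

#' Map a calendar date to its occasion
#'
#' @param scheme An `occasion_scheme`.
#' @param date A `Date` (or string coercible to one).
#' @return Integer occasion 1–6. Dates before the scheme's first window are
#'   an error: a resighting cannot precede the natal season.
#' @export
occasion_of <- function(scheme, date) {
  date <- as.Date(date)
  if (anyNA(date)) stopf("unparseable date in resighting records")
  occ <- findInterval(as.numeric(date), as.numeric(scheme$starts))
  if (any(occ < 1L)) {
    stopf("resighting date(s) precede the natal season of cohort %d: %s",
          scheme$cohort_year,
          paste(utils::head(format(date[occ < 1L]), 5L), collapse = ", "))
  }
  occ
}

# canonical site-class codes, in tie-break priority order (lowest first)
SITE_LEVELS <- c("R", "M1", "M2")

canon_site <- function(x) {
  map <- c("R" = "R", "resident" = "R", "resident-area" = "R",
           "M1" = "M1", "regular-migrant-site" = "M1",
           "M2" = "M2", "irregular-migrant-site" = "M2")
  out <- map[as.character(x)]
  if (anyNA(out)) {
    stopf("unknown site_class value(s): %s",
          paste(unique(x[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Condense one individual's resightings into an encounter history
#'
#' Per occasion 2–5 the event is the state of the latest-dated record inside
#' the window (`"0"` if none); same-date ties break by fixed site-class
#' priority M2 > M1 > R so the coding is a deterministic function of the
#' record set. Occasion 6 is `"1"` iff any record falls after occasion 5.
#' Occasion 1 is forced to `"R"`: every individual is ringed as a chick on
#' the natal colony, so its initial state is known.
#'
#' @param records Data frame with columns `date` and `site_class` (all rows
#'   one individual). May have zero rows.
#' @param scheme The individual's cohort [default_scheme()].
#' @return Character vector of 6 event codes: occasions 1–5 from
#'   `{"R","M1","M2","0"}`, occasion 6 from `{"1","0"}`.
#' @export
condense <- function(records, scheme) {
  events <- c("R", rep("0", 4L), "0")
  if (nrow(records) == 0L) return(events)
  occ <- occasion_of(scheme, records$date)
  site <- canon_site(records$site_class)
  for (o in 2:5) {
    in_o <- which(occ == o)
    if (length(in_o)) {
      d <- as.Date(records$date[in_o])
      pr <- match(site[in_o], SITE_LEVELS)
      pick <- in_o[order(d, pr, decreasing = TRUE)[1L]]
      events[o] <- site[pick]
    }
  }
  if (any(occ == 6L)) events[6] <- "1"
  events
}

#' Build encounter histories for a ringed population
#'
#' Converts raw resighting records into one six-occasion encounter history
#' per ringed individual, including individuals never resighted after
#' ringing (their histories are informative about survival and detection).
#'
#' @param resightings Data frame with columns `id`, `date`, `site_class`.
#' @param ringing Data frame with columns `id` (one row per ringed
#'   individual) and `cohort` (ringing year).
#' @param scheme_factory Function `cohort_year -> occasion_scheme`
#'   (default [default_scheme()]).
#' @return An `encounter_histories` data frame: `id`, `cohort`,
#'   `e1`–`e5` (codes `R`/`M1`/`M2`/`0`) and `e6` (`1`/`0`).
#' @export
build_histories <- function(resightings, ringing,
                            scheme_factory = default_scheme) {
  stopifnot(all(c("id", "cohort") %in% names(ringing)))
  if (nrow(resightings)) {
    stopifnot(all(c("id", "date", "site_class") %in% names(resightings)))
    unknown <- setdiff(unique(as.character(resightings$id)),
                       as.character(ringing$id))
    if (length(unknown)) {
      stopf("resightings refer to unringed individual(s): %s",
            paste(utils::head(unknown, 10L), collapse = ", "))
    }
  }
  ids <- as.character(ringing$id)
  ev <- matrix("0", nrow = length(ids), ncol = 6L)
  by_id <- if (nrow(resightings)) {
    split(resightings, factor(as.character(resightings$id), levels = ids))
  } else NULL
  for (k in seq_along(ids)) {
    sch <- scheme_factory(ringing$cohort[k])
    rec <- if (is.null(by_id)) NULL else by_id[[k]]
    if (is.null(rec)) rec <- data.frame(date = as.Date(character()),
                                        site_class = character())
    ev[k, ] <- condense(rec, sch)
  }
  out <- data.frame(id = ids, cohort = as.integer(ringing$cohort),
                    e1 = ev[, 1], e2 = ev[, 2], e3 = ev[, 3],
                    e4 = ev[, 4], e5 = ev[, 5], e6 = ev[, 6],
                    stringsAsFactors = FALSE)
  class(out) <- c("encounter_histories", "data.frame")
  out
}

#' Read / write encounter histories as CSV
#'
#' @param x An `encounter_histories` data frame.
#' @param path File path.
#' @return `write_histories()` returns `path` invisibly; `read_histories()`
#'   an `encounter_histories` data frame.
#' @export
write_histories <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_histories
#' @export
read_histories <- function(path) {
  df <- utils::read.csv(path, colClasses = c(id = "character"))
  need <- c("id", "cohort", paste0("e", 1:6))
  if (!all(need %in% names(df))) {
    stopf("history file lacks column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  for (j in paste0("e", 1:6)) df[[j]] <- as.character(df[[j]])
  bad <- which(!(df$e2 %in% c(SITE_LEVELS, "0")) |
                 !(df$e6 %in% c("0", "1")))
  if (length(bad)) {
    stopf("malformed event codes at line(s): %s",
          paste(utils::head(bad + 1L, 10L), collapse = ", "))
  }
  df <- df[, need]
  class(df) <- c("encounter_histories", "data.frame")
  df
}

# integer event coding used by the likelihood: occasions 2-5 use
# 0 = not seen, 1 = seen in R, 2 = seen in M1, 3 = seen in M2;
# occasion 6 uses 0/1.
encode_events <- function(histories) {
  ev <- matrix(0L, nrow(histories), 5L)
  for (o in 2:5) {
    ev[, o - 1L] <- match(histories[[paste0("e", o)]],
                          c("0", SITE_LEVELS)) - 1L
  }
  ev[, 5L] <- as.integer(histories$e6)
  if (anyNA(ev)) stopf("invalid event codes in histories")
  ev
}
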