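# Domain types and descriptive estimators for article grammaticalisation
# cycles: stages, typological counts, dated language histories, corpus I/O.

N_STAGES <- 4L

#' Stages of the article grammaticalisation cycle
#'
#' Articles evolve through a four-stage cycle: (0) no article, (1) article
#' identical to its source word (a demonstrative such as *that* for definite
#' articles, the numeral *one* for indefinite articles), (2) article distinct
#' from the source word, (3) article affixed to the noun, after which the
#' affix is lost and the cycle restarts at stage 0. Stages are encoded as the
#' integers 0--3 and a valid history never skips a stage.
#'
#' @param stage integer vector of stage indices.
#' @return `stage_successor` returns the next stage in the cycle;
#'   `validate_stage` returns the input invisibly or throws an error.
#' @examples
#' stage_successor(3L)  # the cycle wraps: affix loss returns to "no article"
#' @export
stage_successor <- function(stage) {
  validate_stage(stage)
  (as.integer(stage) + 1L) %% N_STAGES
}

#' @rdname stage_successor
#' @export
validate_stage <- function(stage) {
  s <- suppressWarnings(as.integer(stage))
  if (length(s) == 0L || anyNA(s) || any(s < 0L | s >= N_STAGES) ||
      any(as.numeric(stage) != s)) {
    stop("stage must be an integer in {0, 1, 2, 3}, got: ",
         paste(utils::head(stage, 4L), collapse = ", "), call. = FALSE)
  }
  invisible(s)
}

#' Cross-linguistic typology of article stages
#'
#' Bundles the number of languages currently observed at each of the four
#' stages of the article cycle, as tabulated from WALS features 37A (definite)
#' and 38A (indefinite).
#'
#' @param counts non-negative integer vector of length 4 (stages 0--3).
#' @param feature label for the feature the counts describe, conventionally
#'   `"definite"` or `"indefinite"`.
#' @return an object of class `typology_counts` with fields `feature`,
#'   `counts` and `total`.
#' @seealso [stationary_frequencies()], [article_typology()]
#' @export
typology_counts <- function(counts, feature = "feature") {
  if (length(counts) != N_STAGES || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be 4 non-negative integers", call. = FALSE)
  }
  counts <- as.integer(round(counts))
  total <- sum(counts)
  if (total <= 0L) stop("typology total must be positive", call. = FALSE)
  structure(list(feature = as.character(feature)[1L],
                 counts = counts, total = total),
            class = "typology_counts")
}

#' @export
print.typology_counts <- function(x, ...) {
  cat("Article typology (", x$feature, "): ", x$total, " languages\n", sep = "")
  tab <- data.frame(stage = 0:3, count = x$counts,
                    fraction = round(x$counts / x$total, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' WALS stage counts for definite and indefinite articles
#'
#' The cross-linguistic distribution of article stages: 243/69/216/92 over
#' 620 languages for the definite article and 296/112/102/24 over 534 for the
#' indefinite article (WALS features 37A/38A collapsed onto the four-stage
#' cycle).
#'
#' @param feature `"definite"` or `"indefinite"`.
#' @return a [typology_counts()] object.
#' @export
article_typology <- function(feature = c("definite", "indefinite")) {
  feature <- match.arg(feature)
  counts <- switch(feature,
                   definite   = c(243L, 69L, 216L, 92L),
                   indefinite = c(296L, 112L, 102L, 24L))
  typology_counts(counts, feature)
}

#' Stationary stage frequencies from typological counts
#'
#' The fraction of surveyed languages currently at each stage,
#' `f_i = counts_i / total`. Under the stationarity assumption these
#' fractions are the equilibrium occupancy of the cycle and set the
#' stage-specific origination rates via [omega_from_mean_rate()].
#'
#' @param counts a [typology_counts()] object.
#' @return numeric vector of length 4 summing to 1.
#' @examples
#' stationary_frequencies(article_typology("definite"))
#' @export
stationary_frequencies <- function(counts) {
  if (!inherits(counts, "typology_counts")) counts <- typology_counts(counts)
  counts$counts / counts$total
}

#' Posterior-mean rate of change from a documented history
#'
#' For a language observed for `t` years with `m` recorded stage changes,
#' the rate of change is estimated as `(m + 1) / t`: the mean of the
#' posterior over Poisson rates under a uniform prior. The estimate is
#' strictly positive even when no change was observed.
#'
#' @param m non-negative integer count(s) of observed changes.
#' @param t observation period(s) in years, positive.
#' @return rate(s) in units of 1/year.
#' @examples
#' estimate_change_rate(0, 1000)  # one change per millennium, in effect
#' @export
estimate_change_rate <- function(m, t) {
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("m must be a non-negative integer count", call. = FALSE)
  }
  if (any(is.na(t)) || any(t <= 0)) {
    stop("observation period t must be positive", call. = FALSE)
  }
  (m + 1) / t
}

#' Pearson chi-squared independence test with Monte Carlo confirmation
#'
#' Tests independence of the rows and columns of a contingency table with the
#' standard Pearson statistic, and complements the asymptotic p-value with a
#' Monte Carlo one: tables are resampled from the multinomial independence
#' model fitted to the observed margins (total count fixed), each resample's
#' statistic is computed against its own margins, and the Monte Carlo p-value
#' is the fraction of resampled statistics at least as large as the observed
#' one.
#'
#' @param table matrix of non-negative integer counts.
#' @param n_mc number of Monte Carlo resamples (0 to skip).
#' @param seed optional integer seed for the resampling.
#' @return list with `statistic`, `df`, `p_asymptotic`, `p_mc` (NA when
#'   `n_mc = 0`) and `n_mc`.
#' @export
independence_test <- function(table, n_mc = 10000L, seed = NULL) {
  x <- as.matrix(table)
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    stop("table must contain non-negative integer counts", call. = FALSE)
  }
  rs <- rowSums(x); cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate margins: every tested row and column needs a positive total",
         call. = FALSE)
  }
  n <- sum(x)
  pearson <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    ok <- e > 0
    sum((tab[ok] - e[ok])^2 / e[ok])
  }
  chi2 <- pearson(x)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  p_asym <- stats::pchisq(chi2, df, lower.tail = FALSE)
  p_mc <- NA_real_
  if (n_mc > 0) {
    if (!is.null(seed)) set.seed(seed)
    p_cell <- as.vector(outer(rs, cs)) / n^2
    sims <- stats::rmultinom(n_mc, n, p_cell)
    stat_mc <- vapply(seq_len(n_mc), function(k) {
      pearson(matrix(sims[, k], nrow = nrow(x)))
    }, numeric(1))
    p_mc <- mean(stat_mc >= chi2 - 1e-12)
  }
  list(statistic = chi2, df = df, p_asymptotic = p_asym,
       p_mc = p_mc, n_mc = n_mc)
}

#' A documented language history
#'
#' One language's contribution to the likelihood: an observation window on a
#' common-era year axis (half-open `[window_start, window_end)`), the stage
#' occupied at the start of the window, and the ordered, dated transitions
#' through the cycle observed within the window. An optional mean historical
#' speaker population size attaches the individual-based theories to the
#' language.
#'
#' @param language language name.
#' @param window_start,window_end observation window in years,
#'   `window_start < window_end`.
#' @param initial_stage stage (0--3) at `window_start`.
#' @param transitions data frame with columns `time` (years, strictly
#'   increasing, inside the window) and `new_stage` (each the cyclic successor
#'   of the previous stage). May have zero rows. An optional
#'   `time_uncertainty` column (years) records dating uncertainty for
#'   interval-dated transitions; the default likelihood does not use it.
#' @param population_size optional positive mean speaker count.
#' @return an object of class `language_history`.
#' @export
language_history <- function(language, window_start, window_end,
                             initial_stage, transitions = NULL,
                             population_size = NA_real_) {
  if (!is.finite(window_start) || !is.finite(window_end) ||
      window_start >= window_end) {
    stop("invalid window for '", language, "': need window_start < window_end",
         call. = FALSE)
  }
  initial_stage <- validate_stage(initial_stage)
  if (is.null(transitions) || nrow(transitions) == 0L) {
    transitions <- data.frame(time = numeric(0), new_stage = integer(0))
  }
  if (!all(c("time", "new_stage") %in% names(transitions))) {
    stop("transitions need columns 'time' and 'new_stage'", call. = FALSE)
  }
  tt <- transitions$time
  ss <- if (length(tt)) validate_stage(transitions$new_stage) else integer(0)
  if (length(tt)) {
    if (any(diff(tt) <= 0)) {
      stop("transition times for '", language,
           "' must be strictly increasing", call. = FALSE)
    }
    if (tt[1L] < window_start || tt[length(tt)] >= window_end) {
      stop("transition times for '", language,
           "' must lie inside [window_start, window_end)", call. = FALSE)
    }
    expected <- (initial_stage + seq_along(ss)) %% N_STAGES
    if (any(ss != expected)) {
      bad <- which(ss != expected)[1L]
      stop("stage skip in '", language, "': transition ", bad, " goes to stage ",
           ss[bad], " but the cyclic successor is ", expected[bad],
           call. = FALSE)
    }
  }
  if (!is.na(population_size) && population_size <= 0) {
    stop("population_size must be positive", call. = FALSE)
  }
  transitions$new_stage <- ss
  structure(list(language = as.character(language)[1L],
                 window_start = as.numeric(window_start),
                 window_end = as.numeric(window_end),
                 initial_stage = initial_stage,
                 transitions = transitions,
                 population_size = as.numeric(population_size)),
            class = "language_history")
}

#' @export
print.language_history <- function(x, ...) {
  cat(sprintf("<language_history> %s: window [%g, %g), start stage %d, %d change(s)",
              x$language, x$window_start, x$window_end, x$initial_stage,
              nrow(x$transitions)), "\n")
  invisible(x)
}

#' Number of changes in a history
#' @param history a [language_history()].
#' @return integer count `m`.
#' @export
n_changes <- function(history) nrow(history$transitions)

#' Final stage of a history
#' @param history a [language_history()].
#' @return stage occupied at the end of the observation window.
#' @export
final_stage <- function(history) {
  (history$initial_stage + n_changes(history)) %% N_STAGES
}

#' A corpus of language histories
#'
#' Languages are treated as independent observations in the likelihood.
#'
#' @param histories list of [language_history()] objects.
#' @param feature feature label the histories describe.
#' @return an object of class `cycle_corpus`.
#' @export
corpus <- function(histories, feature = "feature") {
  if (!length(histories) ||
      !all(vapply(histories, inherits, logical(1), "language_history"))) {
    if (length(histories)) {
      stop("histories must be a list of language_history objects", call. = FALSE)
    }
  }
  structure(list(feature = as.character(feature)[1L], histories = histories),
            class = "cycle_corpus")
}

#' @export
print.cycle_corpus <- function(x, ...) {
  m <- vapply(x$histories, n_changes, integer(1))
  cat(sprintf("<cycle_corpus> %s: %d languages, %d changes (median window %g yr)\n",
              x$feature, length(x$histories), sum(m),
              stats::median(vapply(x$histories,
                                   function(h) h$window_end - h$window_start,
                                   numeric(1)))))
  invisible(x)
}

#' @export
length.cycle_corpus <- function(x) length(x$histories)

.fmt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.10g", x))
}

#' Read and write corpora of language histories
#'
#' The tab-separated format has the columns `language`, `window_start`,
#' `window_end`, `initial_stage`, `transition_time`, `new_stage`,
#' `population_size`, `time_uncertainty`. Each language block starts with a
#' header row carrying the language-level fields (transition columns empty),
#' followed by one row per dated transition (language-level columns empty
#' except the name). A JSON mirror holds one object per language. Writing and
#' re-reading is the identity, and the canonical number formatting makes the
#' round trip byte-stable. Invariant violations (stage skips, unordered
#' times, unknown stage labels) are rejected with the offending line or
#' record named.
#'
#' @param corpus a [corpus()] object.
#' @param path file path; `format` is inferred from the extension
#'   (".json" for JSON, otherwise TSV) unless given.
#' @param format `"tsv"` or `"json"`.
#' @return `read_corpus` returns a [corpus()]; `write_corpus` returns the
#'   path invisibly.
#' @export
write_corpus <- function(corpus, path, format = NULL) {
  stopifnot(inherits(corpus, "cycle_corpus"))
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "tsv")
  if (format == "json") {
    recs <- lapply(corpus$histories, function(h) {
      list(language = h$language,
           window_start = h$window_start, window_end = h$window_end,
           initial_stage = h$initial_stage,
           population_size = if (is.na(h$population_size)) NULL else h$population_size,
           transitions = lapply(seq_len(nrow(h$transitions)), function(i) {
             tr <- list(time = h$transitions$time[i],
                        new_stage = h$transitions$new_stage[i])
             if (!is.null(h$transitions$time_uncertainty) &&
                 !is.na(h$transitions$time_uncertainty[i])) {
               tr$time_uncertainty <- h$transitions$time_uncertainty[i]
             }
             tr
           }))
    })
    jsonlite::write_json(list(feature = corpus$feature, languages = recs),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  header <- c("language", "window_start", "window_end", "initial_stage",
              "transition_time", "new_stage", "population_size",
              "time_uncertainty")
  lines <- paste(header, collapse = "\t")
  lines <- c(paste0("# feature=", corpus$feature), lines)
  for (h in corpus$histories) {
    lines <- c(lines, paste(c(h$language, .fmt_num(h$window_start),
                              .fmt_num(h$window_end), h$initial_stage, "", "",
                              .fmt_num(h$population_size), ""),
                            collapse = "\t"))
    if (nrow(h$transitions)) {
      unc <- h$transitions$time_uncertainty %||% rep(NA_real_, nrow(h$transitions))
      for (i in seq_len(nrow(h$transitions))) {
        lines <- c(lines, paste(c(h$language, "", "", "",
                                  .fmt_num(h$transitions$time[i]),
                                  h$transitions$new_stage[i], "",
                                  .fmt_num(unc[i])),
                                collapse = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_corpus
#' @export
read_corpus <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "tsv")
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    hist <- lapply(obj$languages, function(r) {
      tr <- if (length(r$transitions)) {
        data.frame(
          time = vapply(r$transitions, function(x) as.numeric(x$time), numeric(1)),
          new_stage = vapply(r$transitions, function(x) .parse_stage(x$new_stage, r$language),
                             integer(1)),
          time_uncertainty = vapply(r$transitions, function(x)
            as.numeric(x$time_uncertainty %||% NA_real_), numeric(1)))
      } else NULL
      language_history(r$language, as.numeric(r$window_start),
                       as.numeric(r$window_end),
                       .parse_stage(r$initial_stage, r$language), tr,
                       as.numeric(r$population_size %||% NA_real_))
    })
    return(corpus(hist, obj$feature %||% "feature"))
  }
  lines <- readLines(path)
  feature <- "feature"
  fl <- grep("^# feature=", lines)
  if (length(fl)) feature <- sub("^# feature=", "", lines[fl[1L]])
  body_idx <- which(!grepl("^#", lines))
  if (!length(body_idx)) stop("empty corpus file: ", path, call. = FALSE)
  header_line <- body_idx[1L]
  cols <- strsplit(lines[header_line], "\t", fixed = TRUE)[[1L]]
  need <- c("language", "window_start", "window_end", "initial_stage",
            "transition_time", "new_stage")
  if (!all(need %in% cols)) {
    stop("corpus file ", path, " lacks required columns: ",
         paste(setdiff(need, cols), collapse = ", "), call. = FALSE)
  }
  rows <- body_idx[-1L]
  recs <- list(); order_seen <- character(0)
  for (ln in rows) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    length(f) <- length(cols)
    f[is.na(f)] <- ""
    v <- stats::setNames(as.list(f), cols)
    lang <- v$language
    if (!nzchar(lang)) stop("line ", ln, ": missing language name", call. = FALSE)
    if (nzchar(v$window_start %||% "")) {            # language header row
      if (lang %in% names(recs)) {
        stop("line ", ln, ": duplicate header row for language '", lang, "'",
             call. = FALSE)
      }
      recs[[lang]] <- list(window_start = as.numeric(v$window_start),
                           window_end = as.numeric(v$window_end),
                           initial_stage = .parse_stage(v$initial_stage, lang, ln),
                           population_size =
                             if (nzchar(v$population_size %||% "")) as.numeric(v$population_size) else NA_real_,
                           time = numeric(0), new_stage = integer(0),
                           unc = numeric(0))
      order_seen <- c(order_seen, lang)
    } else {                                          # transition row
      if (!lang %in% names(recs)) {
        stop("line ", ln, ": transition row for '", lang,
             "' before its header row", call. = FALSE)
      }
      recs[[lang]]$time <- c(recs[[lang]]$time, as.numeric(v$transition_time))
      recs[[lang]]$new_stage <- c(recs[[lang]]$new_stage,
                                  .parse_stage(v$new_stage, lang, ln))
      recs[[lang]]$unc <- c(recs[[lang]]$unc,
                            if (nzchar(v$time_uncertainty %||% "")) as.numeric(v$time_uncertainty) else NA_real_)
    }
  }
  hist <- lapply(order_seen, function(lang) {
    r <- recs[[lang]]
    tr <- if (length(r$time)) {
      data.frame(time = r$time, new_stage = r$new_stage, time_uncertainty = r$unc)
    } else NULL
    language_history(lang, r$window_start, r$window_end, r$initial_stage, tr,
                     r$population_size)
  })
  corpus(hist, feature)
}

.parse_stage <- function(x, language, line = NULL) {
  s <- suppressWarnings(as.integer(x))
  if (is.na(s) || s < 0L || s > 3L || as.numeric(x) != s) {
    where <- if (is.null(line)) paste0("language '", language, "'")
             else paste0("line ", line, " (language '", language, "')")
    stop("unknown stage label '", x, "' at ", where, call. = FALSE)
  }
  s
}

#' Read and write typology count files
#'
#' Four-row TSV with columns `stage` and `count`; the feature label is kept
#' in a leading `# feature=` comment.
#'
#' @param counts a [typology_counts()] object.
#' @param path file path.
#' @export
write_typology <- function(counts, path) {
  stopifnot(inherits(counts, "typology_counts"))
  writeLines(c(paste0("# feature=", counts$feature), "stage\tcount",
               paste(0:3, counts$counts, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_typology
#' @export
read_typology <- function(path) {
  lines <- readLines(path)
  feature <- "feature"
  fl <- grep("^# feature=", lines)
  if (length(fl)) feature <- sub("^# feature=", "", lines[fl[1L]])
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = body, sep = "\t")
  if (!all(c("stage", "count") %in% names(tab)) || nrow(tab) != 4L) {
    stop("typology file must have columns stage, count and 4 rows", call. = FALSE)
  }
  counts <- integer(4)
  counts[tab$stage + 1L] <- tab$count
  typology_counts(counts, feature)
}
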