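# Treatment lexicon: melanoma systemic-therapy vocabulary with brand names,
# abbreviations and bounded typo tolerance, plus mention detection.

#' Load a treatment lexicon
#'
#' A lexicon file maps surface forms (generic names, brand names,
#' abbreviations, curated misspellings) to canonical generic drug names and
#' flags drugs that are adjuvant-only when given as monotherapy (interferon,
#' docetaxel). CSV files need columns `canonical`, `variant`, `adjuvant_flag`
#' (one row per surface form); YAML files a list of entries with fields
#' `canonical`, `variants`, `adjuvant_flag`.
#'
#' Invariants enforced at load time: at least one entry; every canonical has
#' at least one surface form (the canonical itself is always added); no
#' surface form maps to two canonicals; the adjuvant flag is consistent
#' within a canonical.
#'
#' @param path Path to a CSV or YAML lexicon file.
#' @return An object of class `treatment_lexicon`.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("lexicon file not found: ", path))
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(path)
    if (length(entries) == 0L) abort("empty lexicon file")
    raw <- bind_rows(lapply(entries, function(e) {
      tibble(
        canonical = as.character(e$canonical),
        variant = as.character(unlist(e$variants %||% e$canonical)),
        adjuvant_flag = isTRUE(e$adjuvant_flag)
      )
    }))
  } else {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  new_lexicon(raw)
}

new_lexicon <- function(raw) {
  required <- c("canonical", "variant", "adjuvant_flag")
  if (nrow(raw) == 0L) abort("empty lexicon file")
  if (!all(required %in% names(raw))) {
    abort("lexicon needs columns canonical, variant, adjuvant_flag")
  }
  raw <- raw |>
    mutate(
      canonical = tolower(trimws(.data$canonical)),
      variant = tolower(trimws(.data$variant)),
      adjuvant_flag = as.logical(.data$adjuvant_flag)
    )
  # every canonical is also a surface form of itself
  self_rows <- raw |>
    distinct(.data$canonical, .data$adjuvant_flag) |>
    mutate(variant = .data$canonical)
  surfaces <- bind_rows(raw, self_rows) |>
    distinct(.data$variant, .data$canonical, .data$adjuvant_flag)
  ambiguous <- surfaces |>
    count(.data$variant) |>
    filter(.data$n > 1L)
  if (nrow(ambiguous) > 0L) {
    abort(paste0(
      "ambiguous lexicon variant(s): ",
      paste(ambiguous$variant, collapse = ", ")
    ))
  }
  flags <- surfaces |> distinct(.data$canonical, .data$adjuvant_flag)
  if (anyDuplicated(flags$canonical)) {
    abort("inconsistent adjuvant_flag within a canonical")
  }
  structure(
    list(
      entries = flags,
      surfaces = surfaces,
      adjuvant = flags$canonical[flags$adjuvant_flag]
    ),
    class = "treatment_lexicon"
  )
}

#' @export
print.treatment_lexicon <- function(x, ...) {
  cat(
    "<treatment_lexicon>", nrow(x$entries), "drugs,",
    nrow(x$surfaces), "surface forms,",
    length(x$adjuvant), "adjuvant-only\n"
  )
  invisible(x)
}

#' Bundled melanoma treatment lexicon
#'
#' NCCN-era systemic therapies for advanced melanoma (checkpoint inhibitors,
#' BRAF/MEK inhibitors, chemotherapies, interleukin-2, T-VEC) with brand
#' names and common abbreviations. Interferon and docetaxel carry the
#' adjuvant flag. This is a curated reconstruction, not a copy of any
#' proprietary list.
#'
#' @return A `treatment_lexicon`.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "melanoma_lexicon.csv",
    package = "forumlot", mustWork = TRUE
  ))
}

.token_regex <- "[a-z0-9]+(?:-[a-z0-9]+)*"

# Tokens of a lowercased string with character offsets.
tokenize_with_positions <- function(lower) {
  m <- gregexpr(.token_regex, lower, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(list(token = character(0), start = integer(0), end = integer(0)))
  }
  len <- attr(m, "match.length")
  list(
    token = substring(lower, m, m + len - 1L),
    start = as.integer(m),
    end = as.integer(m + len - 1L)
  )
}

#' Detect treatment mentions in sentences
#'
#' Case-insensitive whole-token matching against every lexicon surface form,
#' plus a bounded fuzzy pass: tokens of length >= 6 with no exact match are
#' accepted at Levenshtein distance 1 from a surface form of length >= 6 when
#' the nearest canonical is unique (guards against "temozolamide"-style
#' typos without firing on short forms like "ipi"). Multi-word surface forms
#' are matched as phrases. On overlapping candidate spans the leftmost,
#' then longest, match wins. Output is deterministic.
#'
#' @param x Character vector of (cleaned) sentences.
#' @param lexicon A `treatment_lexicon`.
#' @return Tibble with one row per mention: `item` (index into `x`),
#'   `canonical`, `surface` (matched text), `start`, `end` (character span).
#' @export
find_mentions <- function(x, lexicon = default_lexicon()) {
  stopifnot(inherits(lexicon, "treatment_lexicon"))
  empty <- tibble(
    item = integer(), canonical = character(), surface = character(),
    start = integer(), end = integer()
  )
  if (length(x) == 0L) {
    return(empty)
  }
  lower <- tolower(x)
  surf <- lexicon$surfaces
  single <- surf[!grepl(" ", surf$variant), ]
  multi <- surf[grepl(" ", surf$variant), ]
  fuzzy_pool <- single[nchar(single$variant) >= 6L, ]

  toks <- lapply(lower, tokenize_with_positions)

  # one global fuzzy lookup over unique unmatched long tokens
  all_tokens <- unique(unlist(lapply(toks, `[[`, "token")))
  unmatched <- setdiff(all_tokens, single$variant)
  unmatched <- unmatched[nchar(unmatched) >= 6L]
  fuzzy_map <- character(0)
  if (length(unmatched) > 0L && nrow(fuzzy_pool) > 0L) {
    d <- adist(unmatched, fuzzy_pool$variant)
    hit <- vapply(seq_along(unmatched), function(i) {
      di <- d[i, ]
      if (min(di) != 1L) {
        return(NA_character_)
      }
      cans <- unique(fuzzy_pool$canonical[di == 1L])
      if (length(cans) == 1L) cans else NA_character_
    }, character(1))
    fuzzy_map <- stats::setNames(hit, unmatched)
    fuzzy_map <- fuzzy_map[!is.na(fuzzy_map)]
  }

  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    tk <- toks[[i]]
    cand <- NULL
    if (length(tk$token) > 0L) {
      exact_idx <- match(tk$token, single$variant)
      hit <- !is.na(exact_idx)
      cand <- tibble(
        canonical = single$canonical[exact_idx[hit]],
        surface = tk$token[hit],
        start = tk$start[hit],
        end = tk$end[hit]
      )
      fz <- !hit & tk$token %in% names(fuzzy_map)
      if (any(fz)) {
        cand <- bind_rows(cand, tibble(
          canonical = unname(fuzzy_map[tk$token[fz]]),
          surface = tk$token[fz],
          start = tk$start[fz],
          end = tk$end[fz]
        ))
      }
    }
    if (nrow(multi) > 0L) {
      for (j in seq_len(nrow(multi))) {
        rx <- paste0("\\b", gsub("([.|()\\^{}+$*?\\[\\]\\\\])", "\\\\\\1", multi$variant[j]), "\\b")
        mm <- gregexpr(rx, lower[i], perl = TRUE)[[1]]
        if (mm[1] != -1L) {
          len <- attr(mm, "match.length")
          cand <- bind_rows(cand, tibble(
            canonical = multi$canonical[j],
            surface = substring(lower[i], mm, mm + len - 1L),
            start = as.integer(mm),
            end = as.integer(mm + len - 1L)
          ))
        }
      }
    }
    if (is.null(cand) || nrow(cand) == 0L) next
    cand <- cand[order(cand$start, -(cand$end - cand$start)), , drop = FALSE]
    keep <- logical(nrow(cand))
    last_end <- 0L
    for (r in seq_len(nrow(cand))) {
      if (cand$start[r] > last_end) {
        keep[r] <- TRUE
        last_end <- cand$end[r]
      }
    }
    cand <- cand[keep, , drop = FALSE]
    cand$item <- i
    out[[i]] <- cand
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    return(empty)
  }
  select(res, "item", "canonical", "surface", "start", "end")
}

#' Treatment mentions for a sentence table
#'
#' Runs [find_mentions()] over a sentence table and attaches the sentence
#' keys, yielding one row per detected mention.
#'
#' @param records Sentence table from [tokenize_posts()].
#' @param lexicon A `treatment_lexicon`.
#' @return Tibble: `user_id`, `forum`, `post_date`, `post_id`,
#'   `sentence_index`, `canonical`, `surface`, `start`, `end`.
#' @export
mentions_table <- function(records, lexicon = default_lexicon()) {
  hits <- find_mentions(records$text, lexicon)
  bind_cols_safe <- records[hits$item, c(
    "user_id", "forum", "post_date", "post_id", "sentence_index"
  ), drop = FALSE]
  out <- as_tibble(bind_cols_safe)
  out$canonical <- hits$canonical
  out$surface <- hits$surface
  out$start <- hits$start
  out$end <- hits$end
  out
}
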