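## Gene-set overlap statistics: Venn partitioning, cumulative hypergeometric
## overlap tests, and hypergeometric term enrichment with BH correction.

set_members <- function(x) {
  if (is.character(x)) return(unique(x))
  if (!is.null(x$probe_id)) return(unique(x$probe_id))
  abort("Expected a character vector or a tibble with a probe_id column.")
}

resolve_universe <- function(universe, members) {
  if (is.character(universe)) {
    stray <- setdiff(members, universe)
    if (length(stray)) {
      abort(paste0("Set member(s) outside the universe: ",
                   paste(utils::head(stray, 5), collapse = ", ")))
    }
    length(universe)
  } else {
    n <- as.integer(universe)
    if (n < length(unique(members))) {
      abort("`universe` is smaller than the union of the sets.")
    }
    n
  }
}

#' Cumulative hypergeometric overlap test
#'
#' Tests whether two gene sets drawn from a common universe share at least
#' the observed number of members: `p = P(X >= k)` (upper tail, inclusive)
#' for X hypergeometric with population `universe`, `|a|` successes and `|b|`
#' draws.
#'
#' @param a,b Gene sets (character vectors or tibbles with `probe_id`).
#' @param universe Universe size (count) or the universe itself (character
#'   vector, which is also used to validate membership).
#' @return One-row tibble: `set_a_size`, `set_b_size`, `overlap_k`,
#'   `universe_n`, `p_value`.
#' @export
hypergeom_overlap <- function(a, b, universe) {
  ma <- set_members(a); mb <- set_members(b)
  n <- resolve_universe(universe, c(ma, mb))
  k <- length(intersect(ma, mb))
  p <- phyper(k - 1, length(ma), n - length(ma), length(mb),
              lower.tail = FALSE)
  tibble::tibble(set_a_size = length(ma), set_b_size = length(mb),
                 overlap_k = k, universe_n = n, p_value = p)
}

#' Pairwise overlap tests among named gene sets
#'
#' @param sets Named list of gene sets, or a long tibble with `set` and
#'   `probe_id` columns.
#' @param universe Universe size or character vector.
#' @return Tibble with one row per unordered pair: `set_a`, `set_b`, sizes,
#'   `overlap_k`, `universe_n`, `p_value`.
#' @export
overlap_tests <- function(sets, universe) {
  sets <- as_set_list(sets)
  if (length(sets) < 2) abort("Need at least two sets.")
  pairs <- combn(names(sets), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    dplyr::bind_cols(
      tibble::tibble(set_a = pairs[1, i], set_b = pairs[2, i]),
      hypergeom_overlap(sets[[pairs[1, i]]], sets[[pairs[2, i]]], universe))
  })
}

as_set_list <- function(sets) {
  if (is.data.frame(sets)) {
    if (!all(c("set", "probe_id") %in% names(sets))) {
      abort("A set table needs `set` and `probe_id` columns.")
    }
    return(split(sets$probe_id, sets$set))
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be named.")
  }
  lapply(sets, set_members)
}

#' Exhaustive Venn partition of two or three gene sets
#'
#' Counts the disjoint membership regions (3 for two sets, 7 for three); the
#' counts sum to the size of the union.
#'
#' @inheritParams overlap_tests
#' @return Tibble: one logical `in_<name>` column per set, `region` (names
#'   joined with `&`, suffixed `_only` for single-set regions), `count`.
#' @export
venn_partition <- function(sets) {
  sets <- as_set_list(sets)
  if (length(sets) < 2 || length(sets) > 3) {
    abort("venn_partition() takes 2 or 3 sets.")
  }
  all_members <- unique(unlist(sets))
  membership <- vapply(sets, function(s) all_members %in% s,
                       logical(length(all_members)))
  membership <- matrix(membership, ncol = length(sets),
                       dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  key <- apply(membership, 1, paste, collapse = ".")
  combo_key <- apply(combos, 1, paste, collapse = ".")
  counts <- vapply(combo_key, function(k) sum(key == k), integer(1))
  region <- apply(combos, 1, function(r) {
    nm <- paste(names(sets)[unlist(r)], collapse = "&")
    if (sum(unlist(r)) == 1) paste0(nm, "_only") else nm
  })
  out <- tibble::as_tibble(combos)
  names(out) <- paste0("in_", names(sets))
  out$region <- region
  out$count <- unname(counts)
  dplyr::arrange(out, rowSums(dplyr::across(dplyr::starts_with("in_"))),
                 .data$region)
}

#' Hypergeometric term enrichment
#'
#' Over-representation analysis of a query set against an annotation
#' (term -> members) table: one upper-tail hypergeometric p-value per term,
#' sorted ascending, with optional Benjamini-Hochberg q-values across the
#' tested terms.
#'
#' @param query Query gene set (character vector or tibble with `probe_id`).
#' @param annotation Tibble with `term_id` and `probe_id` columns (or a
#'   named list of member vectors).
#' @param universe Universe size or character vector; annotation members must
#'   lie inside a character universe.
#' @param bh Compute BH q-values (default TRUE).
#' @return An `enrich_result` tibble: `term_id`, `term_size`, `hits_k`,
#'   `p_value`, `q_value`.
#' @export
enrich_terms <- function(query, annotation, universe, bh = TRUE) {
  q <- set_members(query)
  if (is.data.frame(annotation)) {
    if (!all(c("term_id", "probe_id") %in% names(annotation))) {
      abort("`annotation` needs term_id and probe_id columns.")
    }
    terms <- split(unique(annotation)[["probe_id"]],
                   unique(annotation)[["term_id"]])
  } else {
    terms <- lapply(annotation, unique)
  }
  if (length(terms) == 0) abort("`annotation` is empty.")
  n <- resolve_universe(universe, c(q, unlist(terms, use.names = FALSE)))
  rows <- purrr::imap_dfr(terms, function(members, term) {
    k <- length(intersect(q, members))
    tibble::tibble(
      term_id = term, term_size = length(members), hits_k = k,
      p_value = phyper(k - 1, length(members), n - length(members),
                       length(q), lower.tail = FALSE))
  })
  rows$q_value <- if (bh) p.adjust(rows$p_value, "BH") else NA_real_
  rows <- dplyr::arrange(rows, .data$p_value, .data$term_id)
  class(rows) <- c("enrich_result", class(rows))
  rows
}
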