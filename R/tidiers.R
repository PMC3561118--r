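## broom-style accessors for the package's result objects.

#' Tidy a SAM differential result
#'
#' @param x A `sam_de` tibble.
#' @param ... Unused.
#' @return A plain tibble of the per-probe results.
#' @method tidy sam_de
#' @export
tidy.sam_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sam_de")
  tibble::as_tibble(out)
}

#' One-row summary of a SAM differential result
#'
#' @inheritParams tidy.sam_de
#' @param min_abs_fold,max_q Gates used for the `n_called` column.
#' @return Tibble: `comparison`, `n_probes`, `s0`, `n_assignments`,
#'   `exhaustive`, `n_called`.
#' @method glance sam_de
#' @export
glance.sam_de <- function(x, min_abs_fold = 1.5, max_q = 0.01, ...) {
  tibble::tibble(
    comparison = attr(x, "comparison"),
    n_probes = nrow(x),
    s0 = attr(x, "s0"),
    n_assignments = attr(x, "n_assignments"),
    exhaustive = attr(x, "exhaustive"),
    n_called = sum(abs(x$fold_change) >= min_abs_fold &
                     x$q_value < max_q))
}

#' Tidy a dependency-scheme result into per-probe flags
#'
#' @param x A `dependency_scheme` object.
#' @param ... Unused.
#' @return Wide tibble: `probe_id`, `direction`, one logical column per
#'   emitted set.
#' @method tidy dependency_scheme
#' @export
tidy.dependency_scheme <- function(x, ...) {
  total <- x$sets$Total
  out <- tibble::tibble(probe_id = x$universe)
  out$direction <- total$direction[match(out$probe_id, total$probe_id)]
  for (nm in names(x$sets)) {
    out[[nm]] <- out$probe_id %in% x$sets[[nm]]$probe_id
  }
  out
}

#' One-row set-size summary of a dependency scheme
#'
#' @inheritParams tidy.dependency_scheme
#' @return Tibble with `n_probes` and one `n_<set>` column per emitted set.
#' @method glance dependency_scheme
#' @export
glance.dependency_scheme <- function(x, ...) {
  sizes <- lapply(x$sets, nrow)
  names(sizes) <- paste0("n_", names(sizes))
  dplyr::bind_cols(tibble::tibble(n_probes = length(x$universe)),
                   tibble::as_tibble(sizes))
}
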