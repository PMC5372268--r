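#' Read gene sets from a GMT file
#'
#' Parses the standard tab-separated GMT dialect: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a line are counted once; blank lines are skipped.
#'
#' @param path path to a GMT file.
#' @return A list of class `gene_set_collection`: `sets` (named list of
#'   character vectors) and `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT format error at line ", i, ": fewer than 3 fields")
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    sets[[fields[1]]] <- members
    descriptions[fields[1]] <- fields[2]
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets; sizes",
      paste(range(lengths(x$sets)), collapse = "-"), "\n")
  invisible(x)
}

# Upper-tail hypergeometric probability P(X >= k) for overlap k of a
# candidate list of size n with a set of size K in a universe of size N.
hypergeom_upper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of a candidate gene list
#'
#' Tests each gene set for over-representation of a candidate list by the
#' upper-tail hypergeometric probability \eqn{P(X \ge k)}, where the universe
#' is the analysis background (typically all genes on the filtered expression
#' matrix), \eqn{K} the set size within the universe, \eqn{n} the candidate
#' list size within the universe, and \eqn{k} the overlap. One-sided
#' over-representation only; raw p-values are reported (an optional
#' Benjamini-Hochberg column can be added), matching the convention of
#' reporting unadjusted enrichment p-values.
#'
#' @param candidates character vector of candidate gene ids; ids outside the
#'   universe are dropped (with a message giving the count).
#' @param collection a [read_gmt()] collection (set members are intersected
#'   with the universe for testing).
#' @param universe character vector of background gene ids.
#' @param adjust add a Benjamini-Hochberg `p_adjust` column (default FALSE).
#' @return data.frame sorted by `p_value`: `set_name`, `N`, `K`, `n`, `k`,
#'   `p_value`, `overlap_genes` (comma-joined), optionally `p_adjust`.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines("setA\tdemo\tg1\tg2\tg3", gmt)
#' enrich(c("g1", "g2"), read_gmt(gmt), universe = paste0("g", 1:10))
#' @export
enrich <- function(candidates, collection, universe, adjust = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe is empty")
  candidates <- unique(as.character(candidates))
  dropped <- sum(!candidates %in% universe)
  if (dropped > 0)
    message("enrich: ", dropped, " candidate gene(s) outside the universe ",
            "dropped")
  candidates <- intersect(candidates, universe)
  if (length(candidates) == 0) {
    warning("no candidate genes remain after intersection with the universe")
    return(data.frame(set_name = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p_value = numeric(0),
                      overlap_genes = character(0),
                      stringsAsFactors = FALSE))
  }
  N <- length(universe)
  n <- length(candidates)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    overlap <- intersect(candidates, members)
    data.frame(set_name = nm, N = N, K = length(members), n = n,
               k = length(overlap),
               p_value = hypergeom_upper_tail(length(overlap),
                                              length(members), n, N),
               overlap_genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
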