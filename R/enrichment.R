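#' Construct an annotation catalog
#'
#' Maps category ids (pathways, processes) to member protein sets.
#'
#' @param members named list of character vectors: category id ->
#'   member proteins. Categories must be non-empty.
#' @param labels optional named character vector of display labels.
#' @return object of class `annotation_catalog`.
#' @export
annotation_catalog <- function(members, labels = NULL) {
  if (!length(members) || is.null(names(members)))
    stop("members must be a non-empty named list")
  if (any(!lengths(members))) stop("categories must be non-empty")
  members <- lapply(members, unique)
  structure(list(members = members, labels = labels),
            class = "annotation_catalog")
}

#' Read an annotation catalog
#'
#' Accepts either a two-column delimited file (`category_id`,
#' `protein_id`; header optional but recommended) or a GMT file
#' (category, description, members... per line).
#'
#' @param path file path; `.gmt` selects the GMT reader.
#' @param labels optional named character vector of category labels.
#' @return an [annotation_catalog()].
#' @export
read_annotation_catalog <- function(path, labels = NULL) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    members <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(members) <- vapply(fields, `[[`, character(1), 1)
    lab <- vapply(fields, `[[`, character(1), 2)
    names(lab) <- names(members)
    return(annotation_catalog(members, labels = lab))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("category_id", "protein_id") %in% names(df)))
    stop("catalog needs columns category_id and protein_id")
  members <- split(df$protein_id, df$category_id)
  annotation_catalog(members, labels = labels)
}

#' Hypergeometric over-representation test
#'
#' For each category, the upper-tail hypergeometric probability of
#' observing at least the attained overlap between the query set and
#' the category within the given universe, with Benjamini-Hochberg
#' adjustment across categories. One-sided: only over-representation is
#' scored.
#'
#' @param query character vector of proteins of interest (must be a
#'   subset of `universe`).
#' @param catalog an [annotation_catalog()]; members outside `universe`
#'   are ignored.
#' @param universe character vector: all proteins that could have been
#'   detected (typically every quantified protein).
#' @return data frame sorted by adjusted p: `category`, `overlap` (k),
#'   `category_size` (K), `query_size` (n), `universe_size` (N),
#'   `expected`, `p`, `q`.
#' @export
enrich <- function(query, catalog, universe) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query)) stop("query must be non-empty")
  if (!length(universe)) stop("universe must be non-empty")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(catalog$members), function(cat) {
    mem <- intersect(catalog$members[[cat]], universe)
    K <- length(mem)
    if (!K) return(NULL)
    k <- length(intersect(mem, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cat, overlap = k, category_size = K,
               query_size = n, universe_size = N, expected = n * K / N,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no catalog category intersects the universe")
  out$q <- stats::p.adjust(out$p, method = "BH")
  if (!is.null(catalog$labels))
    out$label <- unname(catalog$labels[out$category])
  out[order(out$q, out$p), , drop = FALSE]
}
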