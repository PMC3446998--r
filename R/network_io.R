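# Edge-table I/O and the directed interaction-network container.
#
# The network is deliberately minimal: an ordered node set plus a
# deduplicated (source, target) edge matrix. Interactions are unweighted —
# PIDS magnitudes assert direction qualitatively and are discarded once an
# edge passes the threshold filter.

#' Construct a directed interaction network
#'
#' Builds the package's network container from parallel source/target
#' vectors. Self-interactions are dropped with a warning (they would put
#' probability mass on a node's own dangling/degree bookkeeping), duplicate
#' (source, target) pairs collapse to a single unweighted edge, and nodes
#' are ordered lexicographically (C collation) so downstream matrices and
#' rank tie-breaks are deterministic.
#'
#' @param source,target Character vectors of protein identifiers, equal
#'   length, elements non-empty.
#' @return An object of class `interaction_network` with elements `nodes`
#'   (ordered character vector), `edges` (two-column character matrix),
#'   `n_nodes` and `n_edges`.
#' @examples
#' net <- interaction_network(c("P1", "P1"), c("P2", "P3"))
#' net$n_edges
#' @export
interaction_network <- function(source, target) {
  source <- as.character(source)
  target <- as.character(target)
  if (length(source) != length(target)) {
    stop("source and target must have equal length")
  }
  ok <- nzchar(source) & nzchar(target) & !is.na(source) & !is.na(target)
  if (!all(ok)) stop("protein identifiers must be non-empty strings")
  self <- source == target
  if (any(self)) {
    warning(sprintf("dropping %d self-interaction(s)", sum(self)))
    source <- source[!self]
    target <- target[!self]
  }
  if (length(source) == 0L) {
    stop("empty network: no edges remain after filtering")
  }
  key <- paste(source, target, sep = "\r")
  keep <- !duplicated(key)
  source <- source[keep]
  target <- target[keep]
  ord <- order(source, target, method = "radix")
  edges <- cbind(source = source[ord], target = target[ord])
  nodes <- lex_sort(unique(c(edges[, 1L], edges[, 2L])))
  structure(
    list(nodes = nodes, edges = edges,
         n_nodes = length(nodes), n_edges = nrow(edges)),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d proteins, %d directed edges\n",
              x$n_nodes, x$n_edges))
  invisible(x)
}

#' Read a PIDS-scored edge table into a directed network
#'
#' Parses a tab-separated table with header columns `source`, `target` and
#' `pids` (extra columns are ignored; lines starting with `#` are treated
#' as comments) and keeps edges whose PIDS value is *strictly* greater than
#' `threshold` — the convention for asserting a signal-flow direction.
#' Edges at exactly the threshold are excluded.
#'
#' @param path Path to the TSV file, or a character vector of lines, or a
#'   connection.
#' @param threshold Minimum (exclusive) PIDS value for an edge to be kept.
#'   Default 2.0.
#' @return An [interaction_network()].
#' @examples
#' lines <- c("source\ttarget\tpids", "P1\tP2\t2.5", "P2\tP3\t2.0")
#' read_edge_table(lines)
#' @export
read_edge_table <- function(path, threshold = 2.0) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  raw <- if (inherits(path, "connection")) {
    readLines(path)
  } else if (is.character(path) && length(path) == 1L && file.exists(path)) {
    readLines(path)
  } else if (is.character(path)) {
    path
  } else {
    stop("path must be a file path, a connection or a character vector")
  }
  lineno <- seq_along(raw)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  raw <- raw[keep]
  lineno <- lineno[keep]
  if (length(raw) < 1L) stop("edge table has no header line")
  fields <- strsplit(raw, "\t", fixed = TRUE)
  header <- trimws(fields[[1L]])
  needed <- c("source", "target", "pids")
  idx <- match(needed, tolower(header))
  if (anyNA(idx)) {
    stop("edge table header must contain columns source, target, pids")
  }
  body <- fields[-1L]
  body_ln <- lineno[-1L]
  nf <- lengths(body)
  bad <- which(nf < max(idx))
  if (length(bad)) {
    stop(sprintf("malformed row at line %d: expected at least %d fields, got %d",
                 body_ln[bad[1L]], max(idx), nf[bad[1L]]))
  }
  if (length(body) == 0L) stop("empty network: edge table has no data rows")
  src <- vapply(body, `[[`, "", idx[1L])
  tgt <- vapply(body, `[[`, "", idx[2L])
  pids <- suppressWarnings(as.numeric(vapply(body, `[[`, "", idx[3L])))
  bad <- which(is.na(pids))
  if (length(bad)) {
    stop(sprintf("malformed row at line %d: pids value is not numeric",
                 body_ln[bad[1L]]))
  }
  sel <- pids > threshold
  if (!any(sel)) {
    stop(sprintf("empty network: no edge has pids > %g", threshold))
  }
  interaction_network(src[sel], tgt[sel])
}

#' Write a ranking result as a TSV table
#'
#' Writes one row per protein, sorted by rank position, with columns
#' `rank`, `protein_id`, `score` and `percent`. Scores are printed with 17
#' significant digits so that a write/read round trip reproduces the
#' ranking exactly. Optional `header` lines are emitted as `# key=value`
#' provenance comments.
#'
#' @param result A `ranking_result` (see [pagerank()]).
#' @param path Output file path or connection.
#' @param header Optional named character/numeric vector of provenance
#'   key=value pairs.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(result, path, header = NULL) {
  stopifnot(inherits(result, "ranking_result"))
  if (length(result$scores) == 0L) stop("ranking result is empty")
  meta <- c(
    method = result$method, alpha = result$alpha,
    dangling_policy = result$dangling_policy,
    iterations_used = result$iterations_used,
    converged = tolower(as.character(result$converged))
  )
  if (!is.null(header)) meta <- c(meta, header)
  ord <- order(result$positions)
  ids <- names(result$scores)[ord]
  lines <- c(
    sprintf("# %s=%s", names(meta), as.character(meta)),
    "rank\tprotein_id\tscore\tpercent",
    sprintf("%d\t%s\t%.17g\t%.17g",
            result$positions[ord], ids,
            unname(result$scores[ord]), unname(result$percent[ord]))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a ranking TSV back into a ranking result
#'
#' Inverse of [write_ranking()]. Provenance comments (`# key=value`) are
#' parsed back into the result's metadata where recognised.
#'
#' @param path File path, connection or character vector of lines.
#' @return A `ranking_result`.
#' @export
read_ranking <- function(path) {
  raw <- if (is.character(path) && length(path) == 1L && file.exists(path)) {
    readLines(path)
  } else if (inherits(path, "connection")) {
    readLines(path)
  } else {
    as.character(path)
  }
  hdr <- raw[grepl("^#", raw)]
  body <- raw[!grepl("^#", raw) & nzchar(raw)]
  meta <- list()
  m <- regmatches(hdr, regexec("^#\\s*([^=]+)=(.*)$", hdr))
  for (mm in m) if (length(mm) == 3L) meta[[trimws(mm[2L])]] <- trimws(mm[3L])
  cols <- strsplit(body, "\t", fixed = TRUE)
  header <- cols[[1L]]
  ii <- match(c("rank", "protein_id", "score"), header)
  if (anyNA(ii)) stop("ranking table must have columns rank, protein_id, score")
  dat <- cols[-1L]
  if (length(dat) == 0L) stop("ranking table has no data rows")
  ids <- vapply(dat, `[[`, "", ii[2L])
  scores <- as.numeric(vapply(dat, `[[`, "", ii[3L]))
  names(scores) <- ids
  new_ranking_result(
    scores = scores,
    method = if (!is.null(meta$method)) meta$method else "unknown",
    iterations_used = if (!is.null(meta$iterations_used))
      as.integer(meta$iterations_used) else NA_integer_,
    converged = if (!is.null(meta$converged))
      identical(meta$converged, "true") else NA,
    alpha = if (!is.null(meta$alpha)) as.numeric(meta$alpha) else NA_real_,
    dangling_policy = if (!is.null(meta$dangling_policy))
      meta$dangling_policy else "unknown"
  )
}
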