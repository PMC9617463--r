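#' Read a scaffold graph from TSV
#'
#' The format is one edge per line, `u<TAB>v<TAB>kind[<TAB>weight]`, with
#' `kind` either `M` (matching edge, weight column ignored) or `L` (link edge,
#' non-negative numeric weight required). Lines starting with `#` and blank
#' lines are skipped. Vertex names must be non-empty and contain no
#' whitespace; duplicate unordered pairs and negative weights are rejected.
#'
#' @param path file to read.
#' @return A `scaffold_graph`.
#' @seealso [write_scaffold_tsv()]
#' @export
read_scaffold_tsv <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- matrix(character(0), ncol = 2L)
  l <- matrix(character(0), ncol = 2L)
  w <- numeric(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed line (need u, v, kind): '", ln, "'")
    u <- f[1L]; v <- f[2L]; kind <- f[3L]
    if (!nzchar(u) || !nzchar(v) || grepl("[[:space:]]", paste0(u, v))) {
      stop("vertex names must be non-empty and whitespace-free: '", ln, "'")
    }
    if (u == v) stop("loop edge at vertex '", u, "'")
    if (kind == "M") {
      m <- rbind(m, c(u, v))
    } else if (kind == "L") {
      if (length(f) < 4L) stop("link edge without weight: '", ln, "'")
      wt <- suppressWarnings(as.numeric(f[4L]))
      if (is.na(wt)) stop("non-numeric weight: '", ln, "'")
      if (wt < 0) stop("negative weight on link edge {", u, ", ", v, "}")
      l <- rbind(l, c(u, v))
      w <- c(w, wt)
    } else {
      stop("unknown edge kind '", kind, "' (expected M or L)")
    }
  }
  keys <- edge_keys(as_edge_matrix(rbind(m, l), "edges"))
  if (anyDuplicated(keys)) {
    k <- strsplit(keys[duplicated(keys)][1L], "\r", fixed = TRUE)[[1L]]
    stop("duplicate edge {", k[1L], ", ", k[2L], "} in TSV (graph is simple)")
  }
  scaffold_graph(matching = m, links = l, weights = w)
}

#' Write a scaffold graph to TSV
#'
#' @param g a `scaffold_graph`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @seealso [read_scaffold_tsv()]
#' @export
write_scaffold_tsv <- function(g, path) {
  out <- c(
    paste0("# scaffold graph: ", length(g$vertices), " vertices, ",
           nrow(g$matching), " matching edges, ", nrow(g$links),
           " link edges"),
    sprintf("%s\t%s\tM", g$matching[, 1L], g$matching[, 2L]),
    sprintf("%s\t%s\tL\t%.12g", g$links[, 1L], g$links[, 2L], g$weights)
  )
  writeLines(out, path)
  invisible(path)
}

#' Write a solution decomposition as text
#'
#' One element per line (`P v1 v2 ...` for paths, `C v1 v2 ...` for cycles)
#' followed by a summary line `# sigma_p=<int> sigma_c=<int> weight=<num>`.
#'
#' @param d a `solution_decomposition` (see [decompose_solution()]).
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_solution <- function(d, path) {
  out <- c(
    vapply(d$paths, function(p) paste(c("P", p), collapse = " "), character(1)),
    vapply(d$cycles, function(p) paste(c("C", p), collapse = " "), character(1)),
    sprintf("# sigma_p=%d sigma_c=%d weight=%.12g",
            d$sigma_p, d$sigma_c, d$weight)
  )
  writeLines(out, path)
  invisible(path)
}

#' Read a solution text file
#'
#' Parses the format written by [write_solution()]. The returned sequences can
#' be turned back into a set of link edges against a graph with
#' [solution_edges_from_elements()].
#'
#' @param path file to read.
#' @return List with `paths`, `cycles` (vertex sequences) and `summary`
#'   (named numeric vector with `sigma_p`, `sigma_c`, `weight`, or `NULL` if
#'   no summary line is present).
#' @export
read_solution <- function(path) {
  lines <- readLines(path)
  paths <- list(); cycles <- list(); summary <- NULL
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, gregexpr("[a-z_]+=[-0-9.eE+]+", ln))[[1L]]
      if (length(m)) {
        kv <- strsplit(m, "=", fixed = TRUE)
        summary <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                                   vapply(kv, `[`, "", 1L))
      }
      next
    }
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (f[1L] == "P") paths <- c(paths, list(f[-1L]))
    else if (f[1L] == "C") cycles <- c(cycles, list(f[-1L]))
    else stop("malformed solution line: '", ln, "'")
  }
  list(paths = paths, cycles = cycles, summary = summary)
}

#' Recover the link-edge set of listed path/cycle elements
#'
#' @param g a valid `scaffold_graph`.
#' @param paths,cycles lists of vertex sequences as produced by
#'   [decompose_solution()] or [read_solution()].
#' @return Canonical 2-column matrix of link edges.
#' @export
solution_edges_from_elements <- function(g, paths = list(), cycles = list()) {
  mk <- edge_keys(g$matching)
  res <- matrix(character(0), ncol = 2L)
  add_element <- function(el, is_cycle) {
    n <- length(el)
    if (n < 2L) return(invisible(NULL))
    pairs <- cbind(el, c(el[-1L], el[1L]))
    if (!is_cycle) pairs <- pairs[-n, , drop = FALSE]
    pairs <- as_edge_matrix(pairs, "element")
    link <- !(edge_keys(pairs) %in% mk)
    res <<- rbind(res, pairs[link, , drop = FALSE])
  }
  for (el in paths) add_element(el, FALSE)
  for (el in cycles) add_element(el, TRUE)
  res <- as_edge_matrix(res, "solution")
  res[order(res[, 1L], res[, 2L]), , drop = FALSE]
}
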