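#' Read and write temporal edge lists and restored sequences
#'
#' The on-disk format is one edge per line,
#' `u<TAB>v[<TAB>arrival[<TAB>snapshot]]`, with `#`-prefixed comment
#' lines; node ids are opaque strings and arrival positions are 1-based.
#'
#' @name io
NULL

#' Read a temporal network from an edge-list file
#'
#' @param path file with whitespace-separated columns
#'   `u v [arrival] [snapshot]`.
#' @return a [temporal_network]; rows are reordered into arrival order
#'   when an arrival column is present.
#' @export
read_temporal_edgelist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("no edge lines in ", path)
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  nf <- lengths(parts)
  if (any(nf < 2 | nf > 4)) {
    bad <- keep[which(nf < 2 | nf > 4)[1]]
    stop("malformed line ", bad, " in ", path)
  }
  if (length(unique(nf)) > 1)
    stop("inconsistent column counts in ", path)
  u <- vapply(parts, `[`, "", 1)
  v <- vapply(parts, `[`, "", 2)
  for (r in which(u == v))
    stop("self-loop at line ", keep[r], " in ", path)
  arrival <- NULL; snapshot <- NULL
  if (nf[1] >= 3) {
    arrival <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3)))
    if (any(is.na(arrival))) {
      bad <- keep[which(is.na(arrival))[1]]
      stop("non-integer arrival at line ", bad, " in ", path)
    }
    if (!setequal(arrival, seq_along(arrival)))
      stop("arrival positions must be a permutation of 1..E in ", path)
  }
  if (nf[1] == 4) {
    snapshot <- suppressWarnings(as.integer(vapply(parts, `[`, "", 4)))
    if (any(is.na(snapshot))) stop("non-integer snapshot label in ", path)
  }
  ord <- if (is.null(arrival)) seq_along(u) else order(arrival)
  dup <- duplicated(edge_key(u, v))
  if (any(dup)) stop("duplicate edge at line ", keep[which(dup)[1]],
                     " in ", path)
  temporal_network(cbind(u[ord], v[ord]),
                   snapshot = if (is.null(snapshot)) NULL else snapshot[ord])
}

#' Write a temporal network to an edge-list file
#'
#' @param net a [temporal_network].
#' @param path output file.
#' @export
write_temporal_edgelist <- function(net, path) {
  E <- n_edges(net)
  cols <- list(net$edges[, 1], net$edges[, 2], seq_len(E))
  if (!is.null(net$snapshot)) cols <- c(cols, list(net$snapshot))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c("# u\tv\tarrival" %+%
                 (if (is.null(net$snapshot)) "" else "\tsnapshot"),
               lines), path)
  invisible(path)
}

`%+%` <- function(a, b) paste0(a, b)

#' Write a restored sequence (and optional error report)
#'
#' Writes one line per edge, `u<TAB>v<TAB>alpha_hat<TAB>borda`; when a
#' report is given, a JSON file with the overall error, Kendall tau,
#' Spearman rho and (when supplied) the theoretical error is written next
#' to it.
#'
#' @param restored a `restored_sequence`.
#' @param net the [temporal_network] the sequence indexes.
#' @param path output TSV path.
#' @param report optional `error_report`.
#' @param x optional pairwise accuracy for the theory comparison.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(restored, net, path, report = NULL, x = NULL) {
  E <- n_edges(net)
  if (length(restored$positions) != E)
    stop("sequence length does not match network")
  lines <- paste(net$edges[, 1], net$edges[, 2], restored$positions,
                 restored$borda, sep = "\t")
  writeLines(c("# u\tv\talpha_hat\tborda", lines), path)
  if (!is.null(report)) {
    rep_list <- list(E = report$E, overall_error = report$overall_error,
                     kendall_tau = report$kendall_tau,
                     spearman_rho = report$spearman_rho)
    if (!is.null(x)) {
      rep_list$x <- x
      rep_list$theory_error <- theoretical_error(x, report$E)
    }
    jsonlite::write_json(rep_list, paste0(path, ".report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a restored sequence written by [write_sequence]
#' @param path TSV path.
#' @return a `restored_sequence` (positions in file row order).
#' @export
read_sequence <- function(path) {
  d <- utils::read.table(path, sep = "\t", comment.char = "#",
                         col.names = c("u", "v", "alpha_hat", "borda"),
                         colClasses = c("character", "character",
                                        "integer", "integer"))
  restore_sequence(d$borda, source = path)
}

#' Generate a synthetic network by model name
#'
#' Convenience dispatcher over [generate_ba], [generate_pso] and
#' [generate_fitness].
#'
#' @param model `"ba"`, `"pso"` or `"fitness"` (case-insensitive).
#' @param n_nodes,m,seed generator parameters.
#' @param ... model-specific parameters (`temperature`, `beta`,
#'   `fitness_fun`).
#' @return a [temporal_network].
#' @export
generate_network <- function(model, n_nodes, m, seed, ...) {
  switch(tolower(model),
         ba = generate_ba(n_nodes, m, seed),
         pso = generate_pso(n_nodes, m, seed, ...),
         fitness = generate_fitness(n_nodes, m, seed, ...),
         stop("unknown model: ", model))
}
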