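#' Read a protein-protein interaction network from an edge list
#'
#' Parses a tab- or whitespace-delimited two-column edge list into an
#' undirected simple igraph. Lines starting with \code{#} are ignored, extra
#' trailing columns are silently dropped, so interaction-database exports
#' reduced to two id columns load directly. Self-interactions and repeated
#' interactions (in either orientation) are removed, as is conventional when
#' preparing a PIN; the counts of dropped records are reported via
#' \code{message()}.
#'
#' Identifiers are stripped of surrounding whitespace and otherwise compared
#' case-sensitively (yeast ORF names are case-sensitive by convention).
#'
#' @param path path to the edge-list file.
#' @return an undirected simple \code{igraph} whose vertices carry protein
#'   ids in \code{$name}. Endpoints of dropped self-loops remain as
#'   (possibly isolated) vertices.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "A\tA", "A\tC"), f)
#' g <- readNetwork(f)
#' igraph::ecount(g)  # 2: the B-A duplicate and A-A self-loop are dropped
#' @export
readNetwork <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop("line ", idx[which(nf < 2L)[1L]],
         ": expected at least 2 columns in edge list")
  u <- vapply(fields, `[`, character(1), 1L)
  v <- vapply(fields, `[`, character(1), 2L)
  self <- u == v
  key <- edgeKey(u, v)
  dup <- duplicated(key) & !self
  n_self <- sum(self)
  n_dup <- sum(dup)
  if (n_self > 0L) message("readNetwork: dropped ", n_self, " self-interaction(s)")
  if (n_dup > 0L) message("readNetwork: dropped ", n_dup, " repeated interaction(s)")
  nodes <- unique(c(u, v))
  el <- cbind(u, v)[!(self | dup), , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (nrow(el) > 0L)
    g <- igraph::add_edges(g, t(el))
  g
}

#' Read a gene expression matrix
#'
#' Reads a tab-delimited table whose first row holds sample labels and whose
#' subsequent rows hold a protein/gene id followed by one numeric value per
#' sample.
#'
#' @param path path to the expression file.
#' @return numeric matrix, rows named by protein id, columns by sample label.
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("expression file is empty (no header)")
  samples <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  n_s <- length(samples)
  body <- lines[-1L]
  if (length(body) == 0L) {
    m <- matrix(numeric(0), nrow = 0L, ncol = n_s,
                dimnames = list(NULL, samples))
    return(m)
  }
  fields <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != n_s + 1L))
    stop("line ", 1L + which(nf != n_s + 1L)[1L],
         ": expected ", n_s + 1L, " fields (id + one value per sample)")
  ids <- trimws(vapply(fields, `[`, character(1), 1L))
  if (anyDuplicated(ids))
    stop("duplicate protein id in expression file: ",
         ids[duplicated(ids)][1L])
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1L]), numeric(n_s)))
  vals <- matrix(vals, nrow = n_s)  # vapply with n_s = 1 returns a vector
  bad <- which(colSums(is.na(vals)) > 0L)
  if (length(bad))
    stop("line ", 1L + bad[1L], ": non-numeric expression value")
  m <- t(vals)
  dimnames(m) <- list(ids, samples)
  m
}

#' Fill in all-zero expression rows for proteins without expression data
#'
#' Proteins present in the network but absent from the expression matrix get
#' an all-zero expression row; such constant rows yield a Pearson correlation
#' of 0 with every partner downstream (see [edgeCorrelations()]). Existing
#' rows are never altered, and rows for proteins outside the network are
#' retained unchanged.
#'
#' @param net an igraph PIN.
#' @param expr numeric expression matrix with protein rownames.
#' @return expression matrix covering every node of \code{net}.
#' @export
attachMissing <- function(net, expr) {
  if (ncol(expr) == 0L) stop("expression matrix has zero samples")
  nodes <- igraph::V(net)$name
  missing <- setdiff(nodes, rownames(expr))
  if (length(missing) == 0L) return(expr)
  zeros <- matrix(0, nrow = length(missing), ncol = ncol(expr),
                  dimnames = list(missing, colnames(expr)))
  rbind(expr, zeros)
}

#' Read a reference set of essential proteins
#'
#' One identifier per non-empty line; duplicates are collapsed.
#'
#' @param path path to the list file.
#' @return character vector of unique ids.
#' @export
readEssentialSet <- function(path) {
  if (!file.exists(path)) stop("essential-set file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}

#' Write a ranking with per-protein annotations
#'
#' Emits a TSV with columns rank, protein, score, degree (in the original
#' network), node_strength (sum of incident PCC weights) and is_essential
#' (0/1). Scores are written with 12 significant digits so a re-read
#' reproduces them to 1e-9.
#'
#' @param rank an [EssentialRanking-class].
#' @param net the original igraph PIN (for degrees).
#' @param essential character vector of essential ids (may be empty).
#' @param corr an [EdgeCorrelations-class] on \code{net} (for node strength).
#' @param path output file path.
#' @return invisibly, the data.frame written.
#' @export
writeRanking <- function(rank, net, essential, corr, path) {
  tb <- rank@table
  if (!all(tb$protein %in% igraph::V(net)$name))
    stop("ranking contains proteins absent from the network")
  strength <- nodeStrength(net, corr)
  out <- data.frame(
    rank = seq_len(nrow(tb)),
    protein = tb$protein,
    score = sprintf("%.12g", tb$score),
    degree = igraph::degree(net)[tb$protein],
    node_strength = sprintf("%.12g", strength[tb$protein]),
    is_essential = as.integer(tb$protein %in% essential),
    stringsAsFactors = FALSE)
  tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write ranking to ", path, ": ",
                             conditionMessage(e)))
  invisible(out)
}
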