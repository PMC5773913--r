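#' Read a protein-protein interaction network from a two-column edge list
#'
#' Parses a whitespace- or tab-delimited edge list into an undirected simple
#' graph. Self-loops are dropped and duplicate pairs (in either endpoint
#' order) are collapsed to a single edge; counts of both are reported via
#' [message()].
#'
#' @param path Path to the edge-list file. Each non-comment line must carry
#'   at least two tokens; the first two are taken as interacting protein IDs.
#' @param comment_prefix Lines starting with this prefix are skipped
#'   (default `"#"`).
#' @return An undirected, simple [igraph::igraph] object with vertex names
#'   equal to the protein IDs. No edge weights are attached; see
#'   [weight_network()].
#' @seealso [load_biogrid_tab()] for header-bearing BioGRID-style tables.
#' @export
load_edgelist <- function(path, comment_prefix = "#") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment_prefix) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges found in ", path)
  toks <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(vapply(toks, length, integer(1)) < 2L)
  if (length(bad) > 0L) {
    stop("malformed edge line (fewer than 2 fields) at line ", idx[bad[1L]],
         " of ", path)
  }
  a <- trimws(vapply(toks, `[[`, character(1), 1L))
  b <- trimws(vapply(toks, `[[`, character(1), 2L))
  ppi_from_pairs(a, b, source = path)
}

#' Read a BioGRID-style tab-delimited interaction table
#'
#' BioGRID TAB exports carry one interaction per row with a header naming the
#' interactor-ID columns. The identifier dialect (systematic name, official
#' symbol, Entrez ID) varies by export, so the two ID columns are
#' configurable. Rows where either ID is missing (`"-"` or empty) are skipped
#' with a logged count; the cleaning contract then matches [load_edgelist()].
#'
#' @param path Path to the tab-delimited file (header row required).
#' @param id_columns Character vector of length 2 naming the interactor-A and
#'   interactor-B identifier columns.
#' @return An undirected, simple [igraph::igraph] object.
#' @export
load_biogrid_tab <- function(path,
                             id_columns = c("Systematic Name Interactor A",
                                            "Systematic Name Interactor B")) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(length(id_columns) == 2L)
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                           colClasses = "character")
  missing_cols <- setdiff(id_columns, names(tab))
  if (length(missing_cols) > 0L) {
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  a <- trimws(tab[[id_columns[1L]]])
  b <- trimws(tab[[id_columns[2L]]])
  ok <- a != "-" & b != "-" & nzchar(a) & nzchar(b) & !is.na(a) & !is.na(b)
  if (any(!ok)) {
    message("load_biogrid_tab: skipped ", sum(!ok),
            " row(s) with missing interactor IDs")
  }
  if (!any(ok)) stop("no usable interaction rows in ", path)
  ppi_from_pairs(a[ok], b[ok], source = path)
}

# Shared cleaning: drop self-loops, collapse duplicate unordered pairs.
ppi_from_pairs <- function(a, b, source = "input") {
  self <- a == b
  if (any(self)) {
    message("dropped ", sum(self), " self-loop(s) from ", source)
  }
  a2 <- a[!self]
  b2 <- b[!self]
  if (length(a2) == 0L) stop("empty edge set after cleaning in ", source)
  lo <- pmin(a2, b2)
  hi <- pmax(a2, b2)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  if (any(dup)) {
    message("collapsed ", sum(dup), " duplicate pair(s) from ", source)
  }
  g <- igraph::graph_from_edgelist(cbind(lo[!dup], hi[!dup]), directed = FALSE)
  g
}

#' Construct a compartment annotation object
#'
#' @param scl Named list mapping protein ID to a character vector of
#'   compartment IDs (the protein's subcellular localization set).
#' @param sizes Named numeric vector of compartment member counts
#'   (`N_C`, one per compartment). When `NULL`, sizes are computed from
#'   `scl` as the number of distinct annotated proteins per compartment.
#' @return An object of class `compartment_annotation` with elements `scl`
#'   and `sizes`.
#' @export
compartment_annotation <- function(scl, sizes = NULL) {
  stopifnot(is.list(scl))
  scl <- lapply(scl, function(x) unique(as.character(x)))
  if (is.null(sizes)) {
    all_c <- unlist(scl, use.names = FALSE)
    sizes <- table(all_c)
    sizes <- stats::setNames(as.numeric(sizes), names(sizes))
  }
  if (any(sizes < 1)) stop("compartment sizes must be >= 1")
  used <- unique(unlist(scl, use.names = FALSE))
  absent <- setdiff(used, names(sizes))
  if (length(absent) > 0L) {
    stop("compartment(s) annotated but missing from sizes: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  }
  structure(list(scl = scl, sizes = sizes), class = "compartment_annotation")
}

#' @export
print.compartment_annotation <- function(x, ...) {
  cat("compartment_annotation:", length(x$scl), "proteins,",
      length(x$sizes), "compartments\n")
  invisible(x)
}

#' Read protein subcellular-localization annotations
#'
#' Expects a 2-3 column TSV: protein ID, compartment ID, optional numeric
#' confidence. A protein annotated to several compartments appears on several
#' lines. Duplicated (protein, compartment) lines are collapsed (set
#' semantics).
#'
#' @param path Path to the TSV file (no header).
#' @param size_source How compartment member counts are obtained:
#'   `"from_annotations"` (default) counts distinct annotated proteins per
#'   compartment over the whole file; `"from_column"` reads counts from a
#'   third numeric column (the count must repeat on each line of the
#'   compartment).
#' @param min_confidence Optional numeric threshold; when the file carries a
#'   numeric third column and `size_source = "from_annotations"`, lines with
#'   confidence below the threshold are dropped before aggregation.
#' @param restrict_to Optional character vector of protein IDs (typically the
#'   network's vertex names). When supplied, compartment sizes count only
#'   proteins in this set; annotations of other proteins are still retained
#'   in `scl`.
#' @return A [compartment_annotation()] object.
#' @export
load_localization <- function(path,
                              size_source = c("from_annotations", "from_column"),
                              min_confidence = NULL,
                              restrict_to = NULL) {
  size_source <- match.arg(size_source)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty localization file: ", path)
  toks <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(toks, length, integer(1))
  bad <- which(nf < 2L)
  if (length(bad) > 0L) {
    stop("malformed localization line (missing field) at line ", bad[1L],
         " of ", path)
  }
  prot <- trimws(vapply(toks, `[[`, character(1), 1L))
  comp <- trimws(vapply(toks, `[[`, character(1), 2L))
  if (any(!nzchar(prot)) || any(!nzchar(comp))) {
    stop("malformed localization line (empty field) at line ",
         which(!nzchar(prot) | !nzchar(comp))[1L], " of ", path)
  }
  third <- ifelse(nf >= 3L, vapply(toks, function(t) t[[3L]], character(1)), NA)

  sizes <- NULL
  if (size_source == "from_column") {
    if (any(nf < 3L)) stop("size_source = 'from_column' requires a third column")
    n <- suppressWarnings(as.numeric(third))
    if (anyNA(n)) stop("non-numeric size value at line ", which(is.na(n))[1L])
    sizes <- tapply(n, comp, function(v) v[1L])
    sizes <- stats::setNames(as.numeric(sizes), names(sizes))
  } else if (!is.null(min_confidence) && any(nf >= 3L)) {
    conf <- suppressWarnings(as.numeric(third))
    keep <- is.na(conf) | conf >= min_confidence
    if (any(!keep)) {
      message("load_localization: dropped ", sum(!keep),
              " annotation(s) below confidence ", min_confidence)
    }
    prot <- prot[keep]
    comp <- comp[keep]
    if (length(prot) == 0L) stop("no annotations left after confidence filter")
  }

  dup <- duplicated(paste(prot, comp, sep = "\r"))
  prot <- prot[!dup]
  comp <- comp[!dup]
  scl <- split(comp, prot)
  if (is.null(sizes)) {
    if (is.null(restrict_to)) {
      counted <- rep(TRUE, length(prot))
    } else {
      counted <- prot %in% restrict_to
    }
    if (!any(counted)) stop("no annotated proteins in the restriction set")
    sizes <- table(comp[counted])
    sizes <- stats::setNames(as.numeric(sizes), names(sizes))
    # compartments only seen outside the restriction set keep size 1 so that
    # every annotated compartment has a defined (positive) importance
    missing <- setdiff(unique(comp), names(sizes))
    if (length(missing) > 0L) {
      sizes <- c(sizes, stats::setNames(rep(1, length(missing)), missing))
    }
  }
  compartment_annotation(scl, sizes)
}

#' Read a gene-expression matrix
#'
#' First column is the protein/gene ID; the remaining columns are numeric
#' expression values at successive time points. The same ID may occur on
#' multiple rows (multiple probes); for such genes exactly the row with the
#' maximum arithmetic mean is retained, ties broken by first occurrence in
#' file order.
#'
#' @param path Path to a TSV or CSV file. The delimiter is inferred from the
#'   first line (tab wins over comma); a header row is auto-detected (a
#'   header is assumed when the non-ID cells of the first line are not all
#'   numeric).
#' @return A numeric matrix with one row per distinct protein ID (rownames)
#'   and one column per time point.
#' @export
load_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty expression file: ", path)
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  toks <- strsplit(lines, sep, fixed = TRUE)
  first_vals <- suppressWarnings(as.numeric(toks[[1L]][-1L]))
  has_header <- anyNA(first_vals)
  if (has_header) {
    toks <- toks[-1L]
    if (length(toks) == 0L) stop("expression file has a header but no data rows")
  }
  nf <- vapply(toks, length, integer(1))
  if (any(nf < 2L)) {
    stop("expression row ", which(nf < 2L)[1L] + has_header,
         " has no expression values")
  }
  if (length(unique(nf)) != 1L) {
    stop("expression rows have unequal lengths (row ",
         which(nf != nf[1L])[1L] + has_header, ")")
  }
  ids <- trimws(vapply(toks, `[[`, character(1), 1L))
  m <- nf[1L] - 1L
  vals <- matrix(NA_real_, nrow = length(toks), ncol = m)
  for (r in seq_along(toks)) {
    v <- suppressWarnings(as.numeric(toks[[r]][-1L]))
    if (anyNA(v)) {
      stop("non-numeric expression value at row ", r + has_header,
           ", column ", which(is.na(v))[1L] + 1L)
    }
    vals[r, ] <- v
  }
  # multiple probes per gene: keep the profile with the maximum mean,
  # first occurrence winning ties
  means <- rowMeans(vals)
  ord <- order(factor(ids, levels = unique(ids)), -means)
  keep <- ord[!duplicated(ids[ord])]
  keep <- sort(keep)  # restore file order among winners
  out <- vals[keep, , drop = FALSE]
  rownames(out) <- ids[keep]
  out
}

#' Read a list of known essential proteins
#'
#' @param path Path to a text file with one protein ID per non-empty line.
#'   Duplicates are collapsed; surrounding whitespace is stripped.
#' @return Character vector of unique essential-protein IDs.
#' @export
load_essential <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- unique(ids[nzchar(ids)])
  if (length(ids) == 0L) stop("empty essential-protein file: ", path)
  ids
}

#' Write a ranked protein list to a TSV file
#'
#' Proteins are sorted by score in descending order with ties broken by
#' ascending protein ID, so output is deterministic across runs and
#' platforms. Scores are printed with 17 significant digits, which
#' round-trips IEEE doubles exactly.
#'
#' @param scores Named numeric vector of protein scores.
#' @param path Output file path.
#' @param essential Optional character vector of essential-protein IDs; when
#'   given, an `is_essential` column (0/1) is appended.
#' @return Invisibly, the ranking data frame that was written.
#' @seealso [rank_scores()], [read_ranking()]
#' @export
write_ranking <- function(scores, path, essential = NULL) {
  rk <- rank_scores(scores)
  cols <- c("rank", "protein", "score")
  if (!is.null(essential)) {
    rk$is_essential <- as.integer(rk$protein %in% essential)
    cols <- c(cols, "is_essential")
  }
  lines <- c(
    paste(cols, collapse = "\t"),
    do.call(paste, c(lapply(cols, function(cn) {
      if (cn == "score") sprintf("%.17g", rk[[cn]]) else as.character(rk[[cn]])
    }), sep = "\t"))
  )
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) stop("cannot write ranking to ", path, ": ",
                              conditionMessage(e)))
  invisible(rk)
}

#' Read a ranking file written by [write_ranking()]
#'
#' @param path Path to the TSV ranking file.
#' @return Data frame with columns `rank`, `protein`, `score` and, when
#'   present, `is_essential`.
#' @export
read_ranking <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, colClasses = NA, stringsAsFactors = FALSE)
}
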