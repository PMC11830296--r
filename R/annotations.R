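#' Gene-term annotation set
#'
#' Bipartite gene-to-term incidence with optional evidence codes.
#'
#' @param pairs data.frame with columns `gene_id`, `term_id` and optionally
#'   `evidence`. Duplicate (gene, term) pairs are collapsed.
#' @return An object of class `AnnotationSet` with elements `pairs`,
#'   `gene_universe` and `term_universe` (both sorted, unique).
#' @export
AnnotationSet <- function(pairs) {
  if (!all(c("gene_id", "term_id") %in% names(pairs)))
    stop("`pairs` needs columns gene_id and term_id")
  pairs$gene_id <- as.character(pairs$gene_id)
  pairs$term_id <- as.character(pairs$term_id)
  if (!"evidence" %in% names(pairs))
    pairs$evidence <- rep(NA_character_, nrow(pairs))
  key <- paste(pairs$gene_id, pairs$term_id, sep = "\r")
  pairs <- pairs[!duplicated(key), c("gene_id", "term_id", "evidence")]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 gene_universe = sort(unique(pairs$gene_id)),
                 term_universe = sort(unique(pairs$term_id))),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d pairs, %d genes, %d terms\n",
              nrow(x$pairs), length(x$gene_universe), length(x$term_universe)))
  invisible(x)
}

#' Load gene-term annotations
#'
#' Supports a two-column TSV (gene_id, term_id, optional third evidence
#' column) and GAF 2.x. For GAF, only rows with aspect "P" (Biological
#' Process) are kept; the gene ID is taken from the DB Object ID column.
#'
#' @param path file path.
#' @param format `"tsv2col"` or `"gaf"`.
#' @return An `AnnotationSet`.
#' @export
load_annotations <- function(path, format = c("tsv2col", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv2col") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      warning("empty annotation file: ", path)
      return(AnnotationSet(data.frame(gene_id = character(),
                                      term_id = character())))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(nf < 2)
    if (length(bad)) stop("malformed annotation line ", bad[1], " in ", path)
    df <- data.frame(gene_id = vapply(parts, `[[`, "", 1),
                     term_id = vapply(parts, `[[`, "", 2),
                     stringsAsFactors = FALSE)
    if (all(nf >= 3)) df$evidence <- vapply(parts, `[[`, "", 3)
    AnnotationSet(df)
  } else {
    lines <- readLines(path)
    lineno <- seq_along(lines)
    keep <- !startsWith(lines, "!") & nzchar(lines)
    lines <- lines[keep]; lineno <- lineno[keep]
    if (length(lines) == 0) {
      warning("empty GAF file: ", path)
      return(AnnotationSet(data.frame(gene_id = character(),
                                      term_id = character())))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 9)  # aspect lives in column 9
    if (length(bad))
      stop("malformed GAF line ", lineno[bad[1]], " in ", path,
           " (fewer than 9 columns)")
    aspect <- vapply(parts, `[[`, "", 9)
    sel <- aspect == "P"
    df <- data.frame(gene_id = vapply(parts, `[[`, "", 2)[sel],
                     term_id = vapply(parts, `[[`, "", 5)[sel],
                     evidence = vapply(parts, `[[`, "", 7)[sel],
                     stringsAsFactors = FALSE)
    AnnotationSet(df)
  }
}

#' Restrict annotations to experimentally supported evidence
#'
#' Keeps pairs carrying one of the gold-standard evidence codes
#' (EXP, IDA, IMP, IGI, IEP, TAS, IC by default). Input without evidence
#' codes is passed through unchanged with a warning.
#'
#' @param ann an `AnnotationSet`.
#' @param codes character vector of accepted evidence codes.
#' @return The filtered `AnnotationSet`.
#' @export
filter_gold_standard <- function(ann,
    codes = c("EXP", "IDA", "IMP", "IGI", "IEP", "TAS", "IC")) {
  stopifnot(inherits(ann, "AnnotationSet"))
  if (all(is.na(ann$pairs$evidence))) {
    warning("annotations carry no evidence codes; returning unchanged")
    return(ann)
  }
  AnnotationSet(ann$pairs[ann$pairs$evidence %in% codes, , drop = FALSE])
}

#' Ontology DAG
#'
#' @param parents named list mapping each term to the character vector of
#'   its direct parents (empty vector for roots).
#' @return An object of class `OntologyDAG` with elements `terms`,
#'   `parents` and `roots`.
#' @export
OntologyDAG <- function(parents) {
  terms <- union(names(parents), unlist(parents, use.names = FALSE))
  parents <- parents[names(parents) %in% terms]
  missing <- setdiff(terms, names(parents))
  parents[missing] <- replicate(length(missing), character(), simplify = FALSE)
  # cycle check via repeated leaf stripping (Kahn)
  remaining <- parents
  repeat {
    roots_now <- names(remaining)[lengths(remaining) == 0]
    if (length(roots_now) == 0) break
    remaining <- remaining[!names(remaining) %in% roots_now]
    remaining <- lapply(remaining, setdiff, roots_now)
  }
  if (length(remaining) > 0)
    stop("ontology contains a cycle involving: ",
         paste(utils::head(names(remaining), 5), collapse = ", "))
  structure(list(terms = sort(terms), parents = parents,
                 roots = sort(names(parents)[lengths(parents) == 0])),
            class = "OntologyDAG")
}

#' @export
print.OntologyDAG <- function(x, ...) {
  cat(sprintf("OntologyDAG: %d terms, %d roots\n",
              length(x$terms), length(x$roots)))
  invisible(x)
}

#' Read an OBO 1.4 ontology
#'
#' Minimal reader covering `[Term]` stanzas with `id`, `is_a`,
#' `relationship: part_of` and `is_obsolete`. Only is_a and part_of edges
#' are retained, matching the ancestor closure used for GO propagation.
#'
#' @param path OBO file path.
#' @return An `OntologyDAG`.
#' @export
load_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  parents <- list()
  id <- NULL; par <- character(); obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (in_term && !is.null(id) && !obsolete) parents[[id]] <<- par
  }
  for (ln in lines) {
    ln <- trimws(sub("!.*$", "", ln))
    if (ln == "[Term]") { flush(); in_term <- TRUE; id <- NULL
                          par <- character(); obsolete <- FALSE; next }
    if (grepl("^\\[", ln)) { flush(); in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "is_a:"))
      par <- c(par, strsplit(trimws(sub("^is_a:", "", ln)), "\\s+")[[1]][1])
    else if (startsWith(ln, "relationship:")) {
      f <- strsplit(trimws(sub("^relationship:", "", ln)), "\\s+")[[1]]
      if (length(f) >= 2 && f[1] == "part_of") par <- c(par, f[2])
    } else if (startsWith(ln, "is_obsolete:") && grepl("true", ln))
      obsolete <- TRUE
  }
  flush()
  OntologyDAG(parents)
}

#' Ancestors of a term (excluding itself)
#'
#' @param dag an `OntologyDAG`.
#' @param term term ID.
#' @return Character vector of all ancestors.
#' @export
term_ancestors <- function(dag, term) {
  stopifnot(inherits(dag, "OntologyDAG"))
  out <- character(); frontier <- dag$parents[[term]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier], use.names = FALSE)),
                        out)
  }
  out
}

#' Propagate annotations to ancestor terms
#'
#' Every gene annotated to a term becomes annotated to all of that term's
#' ancestors (is_a / part_of closure). Idempotent; evidence codes are
#' carried to propagated pairs from the originating annotation.
#'
#' @param ann an `AnnotationSet`.
#' @param dag an `OntologyDAG` containing every annotated term.
#' @return The propagated `AnnotationSet`.
#' @export
propagate_to_ancestors <- function(ann, dag) {
  stopifnot(inherits(ann, "AnnotationSet"), inherits(dag, "OntologyDAG"))
  unknown <- setdiff(ann$term_universe, dag$terms)
  if (length(unknown))
    stop("annotated terms missing from ontology: ",
         paste(unknown, collapse = ", "))
  anc <- lapply(ann$term_universe, term_ancestors, dag = dag)
  names(anc) <- ann$term_universe
  n_extra <- lengths(anc)[ann$pairs$term_id]
  extra <- data.frame(
    gene_id = rep(ann$pairs$gene_id, n_extra),
    term_id = unlist(anc[ann$pairs$term_id], use.names = FALSE),
    evidence = rep(ann$pairs$evidence, n_extra),
    stringsAsFactors = FALSE)
  AnnotationSet(rbind(ann$pairs, extra))
}

#' Information content of terms
#'
#' `IC(f) = log2(1 / Pr(f))`, where `Pr(f)` is the fraction of genes in the
#' gene universe annotated to term `f`. Terms annotating no gene are
#' absent from the table; a term covering the whole universe has IC 0.
#'
#' @param ann an `AnnotationSet` (typically ancestor-propagated).
#' @param gene_universe optional character vector defining the universe;
#'   defaults to all genes carrying at least one annotation in `ann`.
#' @return Named numeric vector of information content in bits.
#' @export
information_content <- function(ann, gene_universe = NULL) {
  stopifnot(inherits(ann, "AnnotationSet"))
  universe <- gene_universe %||% ann$gene_universe
  if (length(universe) == 0) stop("empty gene universe")
  p <- ann$pairs[ann$pairs$gene_id %in% universe, , drop = FALSE]
  counts <- table(p$term_id)
  ic <- log2(length(universe) / as.numeric(counts))
  names(ic) <- names(counts)
  ic
}

#' Select evaluation terms by annotation count
#'
#' Keeps terms annotated to between `min_genes` and `max_genes` genes
#' (inclusive on both ends).
#'
#' @param ann a propagated `AnnotationSet`.
#' @param min_genes,max_genes inclusive bounds (defaults 20 and 1000).
#' @param gene_universe optional restriction of the genes counted.
#' @return Character vector of term IDs, sorted.
#' @export
select_evaluation_terms <- function(ann, min_genes = 20, max_genes = 1000,
                                    gene_universe = NULL) {
  stopifnot(inherits(ann, "AnnotationSet"))
  p <- ann$pairs
  if (!is.null(gene_universe))
    p <- p[p$gene_id %in% gene_universe, , drop = FALSE]
  counts <- table(p$term_id)
  sort(names(counts)[counts >= min_genes & counts <= max_genes])
}

#' Binary gene x term annotation matrix
#'
#' @param ann an `AnnotationSet`.
#' @param genes,terms row and column universes.
#' @return 0/1 matrix, `genes` x `terms`.
#' @export
annotation_matrix <- function(ann, genes, terms) {
  stopifnot(inherits(ann, "AnnotationSet"))
  A <- matrix(0, length(genes), length(terms),
              dimnames = list(genes, terms))
  p <- ann$pairs[ann$pairs$gene_id %in% genes & ann$pairs$term_id %in% terms, ]
  if (nrow(p)) A[cbind(p$gene_id, p$term_id)] <- 1
  A
}

#' Per-gene annotated term sets
#'
#' @param ann an `AnnotationSet`.
#' @param genes genes to report; `terms` restricts the term universe.
#' @param terms optional term restriction.
#' @return Named list of character vectors.
#' @export
gene_term_sets <- function(ann, genes, terms = NULL) {
  p <- ann$pairs[ann$pairs$gene_id %in% genes, , drop = FALSE]
  if (!is.null(terms)) p <- p[p$term_id %in% terms, , drop = FALSE]
  out <- split(p$term_id, factor(p$gene_id, levels = genes))
  lapply(out, as.character)
}
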