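#' Construct a gene-set annotation
#'
#' @param sets named list: term id -> character vector of gene ids.
#' @param info optional data frame of term metadata with columns `term_id`,
#'   `name`, `namespace`.
#' @return object of class `gene_sets`.
#' @export
gene_sets <- function(sets, info = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(g) sort(unique(as.character(g))))
  if (any(lengths(sets) == 0L)) stop("gene sets must be non-empty")
  if (is.null(info)) {
    info <- data.frame(term_id = names(sets), name = NA_character_,
                       namespace = NA_character_, stringsAsFactors = FALSE)
  } else {
    stopifnot("term_id" %in% names(info))
    info <- merge(data.frame(term_id = names(sets), stringsAsFactors = FALSE),
                  info, by = "term_id", all.x = TRUE, sort = FALSE)
    if (!"name" %in% names(info)) info$name <- NA_character_
    if (!"namespace" %in% names(info)) info$namespace <- NA_character_
    info <- info[match(names(sets), info$term_id),
                 c("term_id", "name", "namespace")]
    rownames(info) <- NULL
  }
  structure(list(sets = sets, info = info), class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("Gene-set annotation:", length(x$sets), "terms,",
      length(unique(unlist(x$sets, use.names = FALSE))), "distinct genes\n")
  cat("  set sizes:", paste(range(lengths(x$sets)), collapse = "-"),
      "(min-max)\n")
  invisible(x)
}

#' @export
length.gene_sets <- function(x) length(x$sets)

#' All genes appearing in an annotation
#' @param ann a [gene_sets()] object.
#' @return sorted character vector of gene ids.
#' @export
annotation_genes <- function(ann) {
  stopifnot(inherits(ann, "gene_sets"))
  sort(unique(unlist(ann$sets, use.names = FALSE)))
}

#' Read a gene-to-term annotation file
#'
#' Two formats are supported: a two-column TSV of (gene_id, term_id) pairs,
#' and GAF 2.x where column 2 (DB object id) and column 5 (term id) are used;
#' GAF rows whose qualifier (column 4) contains `NOT` are skipped, as are
#' malformed lines (with a warning). Duplicate pairs are collapsed.
#'
#' @param path annotation file.
#' @param format `"two_column_tsv"` or `"gaf"`.
#' @return a [gene_sets()] object.
#' @export
read_gene_sets <- function(path, format = c("two_column_tsv", "gaf")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (format == "gaf") lines <- lines[!startsWith(lines, "!")]
  if (length(lines) == 0L) stop("empty annotation file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "two_column_tsv") {
    # tolerate (and skip) a header row naming the columns
    if (length(fields[[1]]) >= 2 &&
        tolower(fields[[1]][1]) %in% c("gene", "gene_id")) {
      fields <- fields[-1]
    }
    bad <- lengths(fields) < 2L
    if (any(bad)) stop("malformed two-column annotation line ",
                       which(bad)[1], " in ", path)
    gene <- vapply(fields, `[`, "", 1L)
    term <- vapply(fields, `[`, "", 2L)
  } else {
    ok <- lengths(fields) >= 5L
    if (any(!ok))
      warning(sum(!ok), " malformed GAF line(s) skipped in ", path)
    fields <- fields[ok]
    qualifier <- vapply(fields, `[`, "", 4L)
    negated <- vapply(strsplit(qualifier, "|", fixed = TRUE),
                      function(x) "NOT" %in% x, logical(1))
    fields <- fields[!negated]
    gene <- vapply(fields, `[`, "", 2L)
    term <- vapply(fields, `[`, "", 5L)
  }
  keep <- nzchar(gene) & nzchar(term)
  if (!any(keep)) stop("no usable annotation pairs in ", path)
  gene_sets(split(gene[keep], term[keep]))
}

#' Write an annotation as a two-column (gene_id, term_id) TSV
#'
#' @param ann a [gene_sets()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(ann, path) {
  stopifnot(inherits(ann, "gene_sets"))
  pairs <- data.frame(
    gene_id = unlist(ann$sets, use.names = FALSE),
    term_id = rep.int(names(ann$sets), lengths(ann$sets)),
    stringsAsFactors = FALSE)
  writeLines(paste(pairs$gene_id, pairs$term_id, sep = "\t"), path)
  invisible(path)
}

#' Parse a minimal OBO ontology
#'
#' Reads `[Term]` stanzas and retains the id, name, namespace, and the
#' `is_a` and `relationship: part_of` parent edges; obsolete terms are
#' dropped. This covers what ancestor propagation needs.
#'
#' @param path OBO file.
#' @return object of class `obo_ontology`: list with `info` (data frame:
#'   term_id, name, namespace) and `parents` (named list term -> parents).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  terms <- list()
  for (i in seq_along(starts)) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    nxt <- which(startsWith(chunk, "["))   # e.g. a trailing [Typedef] stanza
    if (length(nxt)) chunk <- chunk[seq_len(nxt[1] - 1L)]
    field <- function(key) {
      v <- chunk[startsWith(chunk, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", v))
    }
    id <- field("id")[1]
    if (is.na(id) || any(field("is_obsolete") == "true")) next
    isa <- sub(" *!.*$", "", field("is_a"))
    rel <- field("relationship")
    partof <- sub(" *!.*$", "",
                  sub("^part_of +", "", rel[startsWith(rel, "part_of")]))
    terms[[id]] <- list(name = field("name")[1],
                        namespace = field("namespace")[1],
                        parents = unique(c(isa, partof)))
  }
  info <- data.frame(
    term_id = names(terms),
    name = vapply(terms, function(t) t$name %||% NA_character_, ""),
    namespace = vapply(terms, function(t) t$namespace %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  rownames(info) <- NULL
  structure(list(info = info,
                 parents = lapply(terms, `[[`, "parents")),
            class = "obo_ontology")
}

#' @export
print.obo_ontology <- function(x, ...) {
  cat("Ontology:", nrow(x$info), "terms,",
      sum(lengths(x$parents)), "is_a/part_of edges\n")
  invisible(x)
}

# ancestors (excluding the term itself) for every term; errors on a cycle
ontology_ancestors <- function(ontology) {
  parents <- ontology$parents
  anc <- vector("list", length(parents))
  names(anc) <- names(parents)
  state <- setNames(integer(length(parents)), names(parents)) # 0/1/2
  stack <- character(0)
  visit <- function(t) {
    if (!t %in% names(parents)) return(character(0))
    if (state[[t]] == 1L) {
      cyc <- c(stack[which(stack == t)[1]:length(stack)], t)
      stop("cycle detected in ontology: ", paste(cyc, collapse = " -> "))
    }
    if (state[[t]] == 2L) return(anc[[t]])
    state[[t]] <<- 1L
    stack <<- c(stack, t)
    p <- parents[[t]]
    res <- unique(c(p, unlist(lapply(p, visit), use.names = FALSE)))
    stack <<- stack[-length(stack)]
    state[[t]] <<- 2L
    anc[[t]] <<- res
    res
  }
  for (t in names(parents)) visit(t)
  anc
}

#' Propagate annotations to ontology ancestors
#'
#' Every gene annotated to a term becomes annotated to all its is_a/part_of
#' ancestors (the standard true-path rule). The operation is idempotent.
#'
#' @param ann a [gene_sets()] object.
#' @param ontology an [read_obo()] ontology.
#' @return a propagated [gene_sets()] object; ancestor terms absent from the
#'   input annotation are added, and term metadata is taken from the ontology
#'   where available.
#' @export
propagate_annotations <- function(ann, ontology) {
  stopifnot(inherits(ann, "gene_sets"), inherits(ontology, "obo_ontology"))
  anc <- ontology_ancestors(ontology)
  sets <- ann$sets
  for (t in names(ann$sets)) {
    for (p in anc[[t]] %||% character(0)) {
      sets[[p]] <- c(sets[[p]], ann$sets[[t]])
    }
  }
  info <- merge(data.frame(term_id = names(sets), stringsAsFactors = FALSE),
                ontology$info, by = "term_id", all.x = TRUE, sort = FALSE)
  # keep names from the input annotation where the ontology has none
  old <- ann$info[match(info$term_id, ann$info$term_id), ]
  info$name <- ifelse(is.na(info$name), old$name, info$name)
  info$namespace <- ifelse(is.na(info$namespace), old$namespace,
                           info$namespace)
  gene_sets(sets, info)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
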