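#' Construct an expression matrix object
#'
#' Container for a gene x sample numeric matrix with a declared measurement
#' unit. Units: \code{"rsem"} (normalized RNA-Seq abundance), \code{"counts"}
#' (raw integer counts), \code{"log_intensity"} (log-scale microarray
#' intensity), \code{"log2"} (generic log2 scale).
#'
#' @param values numeric matrix, genes in rows, samples in columns, both
#'   dimensions named with unique ids.
#' @param unit one of \code{"rsem"}, \code{"log_intensity"}, \code{"counts"},
#'   \code{"log2"}.
#' @param cohort_label free-text cohort tag carried through results.
#' @return an object of class \code{ExpressionMatrix}: a list with elements
#'   \code{values}, \code{unit}, \code{cohort_label}.
#' @export
expression_matrix <- function(values, unit = c("rsem", "log_intensity", "counts", "log2"),
                              cohort_label = "cohort") {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must have gene rownames and sample colnames")
  if (nrow(values) == 0 && is.null(rownames(values)))
    rownames(values) <- character(0)
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(values)))
    stop("`values` contains non-finite entries")
  if (unit == "counts" && (any(values < 0) || any(values != round(values))))
    stop("counts unit requires non-negative integer values")
  structure(list(values = values, unit = unit, cohort_label = cohort_label),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s': %d genes x %d samples [unit: %s]\n",
              x$cohort_label, nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

# Accept either an ExpressionMatrix or a bare named matrix.
expr_values <- function(X) {
  if (inherits(X, "ExpressionMatrix")) return(X$values)
  if (is.matrix(X) && is.numeric(X)) return(X)
  stop("expected an ExpressionMatrix or a numeric matrix")
}

expr_unit <- function(X) if (inherits(X, "ExpressionMatrix")) X$unit else NA_character_

#' Read a gene x sample expression TSV
#'
#' The file must have a header row of sample ids and gene ids in the first
#' column. Row and column order are preserved.
#'
#' @param path file path.
#' @param unit declared measurement unit (see [expression_matrix()]).
#' @param cohort_label cohort tag.
#' @return an \code{ExpressionMatrix}.
#' @export
read_expression_matrix <- function(path, unit = c("rsem", "log_intensity", "counts", "log2"),
                                   cohort_label = basename(path)) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("expression TSV needs a gene-id column plus >= 1 sample")
  genes <- df[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  if (any(is.na(num) & !is.na(raw))) {
    bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 genes[bad[1]], colnames(raw)[bad[2]]))
  }
  dimnames(num) <- list(genes, colnames(raw))
  expression_matrix(num, unit = unit, cohort_label = cohort_label)
}

#' Write an expression matrix as TSV
#'
#' @param X an \code{ExpressionMatrix} or named numeric matrix.
#' @param path output path.
#' @param gene_col name for the gene-id column.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(X, path, gene_col = "gene_id") {
  V <- expr_values(X)
  df <- data.frame(rownames(V), V, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, fields \code{name<TAB>description<TAB>}
#' member ids. Members are deduplicated; empty sets are dropped with a
#' warning.
#'
#' @param path GMT file path.
#' @param name collection name (defaults to file name).
#' @return a \code{GeneSetCollection}: list with \code{name}, \code{sets}
#'   (named list of character vectors) and \code{source}.
#' @export
read_gene_sets_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >= 1 member", i, length(f)))
    sname <- f[1]
    if (sname %in% names(sets)) stop("duplicate gene-set name: ", sname)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning("dropping empty gene set: ", sname)
      next
    }
    sets[[sname]] <- members
  }
  gene_set_collection(sets, name = name, source = path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of gene ids.
#' @param name collection name.
#' @param source provenance string.
#' @return a \code{GeneSetCollection}.
#' @export
gene_set_collection <- function(sets, name = "collection", source = "in-memory") {
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("all gene sets must be named")
    if (anyDuplicated(names(sets))) stop("gene-set names must be unique")
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  }
  structure(list(name = name, sets = sets, source = source),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection '%s': %d sets (source: %s)\n",
              x$name, length(x$sets), x$source))
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param collection a \code{GeneSetCollection}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_sets_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical covariate / survival TSV
#'
#' Expected columns: \code{sample_id}, \code{age}, \code{gender} (male/female),
#' \code{stage} (1-4, substages like "IIIa" collapsed by major stage number)
#' or a pre-binarized \code{stage_binary}, and outcome pairs
#' \code{os_time}/\code{os_event}, \code{dfi_time}/\code{dfi_event}. Stages
#' 1-2 map to group \code{"1-2"}, stages 3-4 to \code{"3-4"}. Rows with a
#' missing outcome stay in the table and are excluded per model by
#' complete-case handling downstream.
#'
#' @param path TSV path.
#' @return a \code{data.frame} of class \code{ClinicalTable}.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  as_clinical_table(df)
}

#' Validate and normalize a clinical table
#'
#' @param df data.frame with the columns documented in [read_clinical_table()].
#' @return the validated \code{ClinicalTable} data.frame.
#' @export
as_clinical_table <- function(df) {
  if (!"sample_id" %in% names(df)) stop("clinical table needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  if ("gender" %in% names(df)) {
    g <- tolower(as.character(df$gender))
    bad <- setdiff(unique(g[!is.na(g)]), c("male", "female"))
    if (length(bad)) stop("gender must be male/female; found: ", paste(bad, collapse = ", "))
    df$gender <- g
  }
  if (!"stage_binary" %in% names(df) && "stage" %in% names(df)) {
    df$stage_binary <- binarize_stage(df$stage)
  }
  if ("stage_binary" %in% names(df)) {
    sb <- as.character(df$stage_binary)
    bad <- setdiff(unique(sb[!is.na(sb)]), c("1-2", "3-4"))
    if (length(bad)) stop("stage_binary must be '1-2'/'3-4'; found: ", paste(bad, collapse = ", "))
    df$stage_binary <- sb
  }
  for (tcol in intersect(c("os_time", "dfi_time"), names(df))) {
    tv <- suppressWarnings(as.numeric(df[[tcol]]))
    if (any(tv < 0, na.rm = TRUE))
      stop("negative time in column ", tcol)
    df[[tcol]] <- tv
  }
  for (ecol in intersect(c("os_event", "dfi_event"), names(df))) {
    ev <- suppressWarnings(as.numeric(df[[ecol]]))
    if (any(!ev %in% c(0, 1) & !is.na(ev)))
      stop("event indicator in ", ecol, " must be 0/1")
    df[[ecol]] <- ev
  }
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Binarize tumor stage by major stage number
#'
#' Accepts numeric stages 1-4, roman numerals with optional substage letters
#' ("IIIa"), or already-binarized strings. Stages 1-2 -> "1-2"; 3-4 -> "3-4".
#'
#' @param stage vector of stage codes.
#' @return character vector of "1-2"/"3-4" (NA preserved).
#' @export
binarize_stage <- function(stage) {
  s <- trimws(toupper(as.character(stage)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("1-2", "3-4")] <- s[s %in% c("1-2", "3-4")]
  # strip "STAGE " prefixes and substage letters
  s2 <- sub("^STAGE\\s*", "", s)
  s2 <- sub("[A-C]$", "", s2)
  major <- rep(NA_integer_, length(s2))
  major[s2 %in% c("1", "I")] <- 1L
  major[s2 %in% c("2", "II")] <- 2L
  major[s2 %in% c("3", "III")] <- 3L
  major[s2 %in% c("4", "IV")] <- 4L
  out[!is.na(major) & major <= 2] <- "1-2"
  out[!is.na(major) & major >= 3] <- "3-4"
  unknown <- !is.na(s) & nzchar(s) & is.na(out)
  if (any(unknown))
    stop("unrecognized stage value(s): ", paste(unique(s[unknown]), collapse = ", "))
  out
}

#' Write a clinical table as TSV
#' @param clinical a \code{ClinicalTable} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
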