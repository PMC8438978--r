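#' Read and write the core tabular artifacts
#'
#' All artifacts are plain TSV so that a write -> read -> write cycle is
#' byte-identical. Counts are stored with a leading `gene` column; the sample
#' sheet has columns sample, treatment, control_for, class, replicate.
#'
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @return `read_counts`: an integer matrix (genes x samples).
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene") stop("count matrix must start with a 'gene' column")
  if (anyDuplicated(df$gene)) stop("duplicate gene ids in count matrix")
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate sample ids in count matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene
  m
}

#' @rdname io
#' @param counts integer matrix, genes x samples.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @return `read_sample_sheet`: a data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(sample = "character", treatment = "character",
                                  control_for = "character", class = "character",
                                  replicate = "integer"))
  validate_sample_sheet(df)
  df
}

#' @rdname io
#' @param sheet sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_sample_sheet <- function(sheet) {
  need <- c("sample", "treatment", "control_for", "class", "replicate")
  if (!all(need %in% colnames(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$sample)) stop("duplicate sample ids in sample sheet")
  sheet$control_for[is.na(sheet$control_for)] <- ""
  refs <- unique(sheet$control_for[sheet$control_for != ""])
  missing <- setdiff(refs, sheet$treatment)
  if (length(missing))
    stop("control_for references missing control group(s): ",
         paste(missing, collapse = ", "))
  invisible(sheet)
}

# treatments (non-control) with their matched control group ids
treatment_controls <- function(sheet) {
  tr <- sheet[sheet$control_for != "" & !is.na(sheet$control_for), ,
              drop = FALSE]
  pairs <- unique(tr[, c("treatment", "control_for")])
  if (anyDuplicated(pairs$treatment))
    stop("a treatment maps to more than one control group")
  setNames(pairs$control_for, pairs$treatment)
}

#' @rdname io
#' @return `read_de_table`: data.frame gene, treatment, log2fc, p, padj.
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "treatment", "log2fc", "p", "padj")
  if (!all(need %in% colnames(df)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df[, c("gene", "treatment")]))
    stop("DE table has duplicate (gene, treatment) rows")
  df[, need]
}

#' @rdname io
#' @param det DE table data.frame.
#' @export
write_de_table <- function(det, path) {
  write.table(det, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param fc genes x treatments numeric matrix of log2 fold changes.
#' @export
write_fc_matrix <- function(fc, path) {
  df <- data.frame(gene = rownames(fc), fc, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_fc_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids. Duplicate members within a set are collapsed. If a
#' `universe` is given, members outside it are dropped (with a message giving
#' the count) and the universe is attached; otherwise the universe defaults
#' to the union of all members.
#'
#' @param path GMT file path.
#' @param universe optional character vector of valid gene ids.
#' @return a list with elements `sets` (named list of character vectors),
#'   `descriptions` (named character), `universe` (character vector).
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  dropped <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(ln, 1, 60))
    members <- unique(parts[-(1:2)])
    if (!is.null(universe)) {
      keep <- members %in% universe
      dropped <- dropped + sum(!keep)
      members <- members[keep]
    }
    if (length(members)) {
      sets[[parts[1]]] <- members
      desc[parts[1]] <- parts[2]
    }
  }
  if (dropped > 0)
    message(dropped, " gene-set member(s) outside the universe dropped")
  if (is.null(universe)) universe <- unique(unlist(sets))
  list(sets = sets, descriptions = desc, universe = universe)
}

#' @rdname read_gmt
#' @param gsc gene-set collection as returned by `read_gmt`.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$descriptions[nm] %||% "", gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a directed edge list in Cytoscape SIF format
#'
#' Each line is `regulator coexp target` (tab-separated).
#'
#' @param edges data.frame with columns regulator, target.
#' @param path output path.
#' @export
write_sif <- function(edges, path) {
  writeLines(paste(edges$regulator, "coexp", edges$target, sep = "\t"), path)
  invisible(path)
}

#' Write a weight matrix as a sorted sparse triplet TSV
#'
#' Rows are `regulator target weight` triplets for nonzero entries, sorted by
#' decreasing weight (ties by regulator then target id).
#'
#' @param w weight matrix (regulators x targets).
#' @param path output path.
#' @param min_weight write only entries >= this value (default all nonzero).
#' @export
write_weights_sparse <- function(w, path, min_weight = .Machine$double.xmin) {
  idx <- which(w >= min_weight, arr.ind = TRUE)
  df <- data.frame(regulator = rownames(w)[idx[, 1]],
                   target = colnames(w)[idx[, 2]],
                   weight = w[idx], stringsAsFactors = FALSE)
  df <- df[order(-df$weight, df$regulator, df$target), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
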