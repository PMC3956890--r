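#' Read a gene expression matrix
#'
#' Reads a tab-delimited expression table: first column gene id, header row of
#' sample ids, one row per gene, continuous values. Lines starting with
#' \code{#} are skipped. Duplicate gene rows are collapsed by their mean
#' (mirroring probe-to-gene averaging); rows containing missing or non-numeric
#' values are rejected with an error naming the offending line.
#'
#' @param path Path to a tab-delimited file.
#' @return Numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames.
#' @examples
#' f <- tempfile()
#' writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), f)
#' readExpression(f)
#' @export
readExpression <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2)
    stop("expression file needs a header and at least one gene row: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3)
    stop("expression header must list at least 2 samples (line ",
         lineno[1], ")")
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in expression header")
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncol_expect <- length(header)
  gene_ids <- character(length(body))
  values <- matrix(NA_real_, length(body), length(sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncol_expect)
      stop("line ", lineno[i + 1], ": expected ", ncol_expect,
           " fields, found ", length(row))
    gene_ids[i] <- row[1]
    v <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("line ", lineno[i + 1], ", column ", bad + 1,
           ": non-numeric value '", row[bad + 1], "' for gene ", row[1])
    }
    values[i, ] <- v
  }
  if (anyDuplicated(gene_ids)) {
    values <- rowsum(values, gene_ids, reorder = FALSE)
    counts <- as.vector(table(factor(gene_ids, levels = rownames(values))))
    values <- values / counts
    gene_ids <- rownames(values)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Write an expression matrix in the tab-delimited interchange format
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeExpression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  body <- apply(expr, 1, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(expr), body, sep = "\t"), con)
  invisible(path)
}

#' Read a clinical table
#'
#' Columns: sample id, time to distant metastasis (or censoring) in years,
#' binary event indicator (1 = distant metastasis observed). Header row
#' required; \code{#} comments skipped.
#'
#' @param path Path to a tab-delimited file.
#' @return data.frame with columns \code{sample_id}, \code{time},
#'   \code{event}.
#' @export
readClinical <- function(path) {
  d <- utils::read.delim(path, comment.char = "#",
                         colClasses = c("character", "numeric", "numeric"),
                         col.names = c("sample_id", "time", "event"))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample ids in ", path)
  if (any(d$time < 0)) stop("negative follow-up time in ", path)
  if (!all(d$event %in% c(0, 1))) stop("event indicator must be 0 or 1 in ",
                                       path)
  d
}

#' Write a clinical table
#' @param clin data.frame with \code{sample_id}, \code{time}, \code{event}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeClinical <- function(clin, path) {
  utils::write.table(
    data.frame(sample_id = clin$sample_id, time_years = clin$time,
               event = clin$event),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected candidate-pair edge list
#'
#' Each line names an unordered gene pair (two tab- or space-separated ids),
#' typically taken from a protein-protein interaction network. Self-pairs are
#' dropped with a warning and duplicate unordered pairs are collapsed; the
#' counts of both are reported via \code{message}.
#'
#' @param path Path to the edge-list file.
#' @return data.frame with columns \code{gene_a}, \code{gene_b}; one row per
#'   unique unordered pair.
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[\t ]+")
  bad <- lengths(parts) != 2
  if (any(bad))
    stop("edge list line must hold exactly two gene ids: '",
         lines[which(bad)[1]], "'")
  a <- vapply(parts, `[`, "", 1)
  b <- vapply(parts, `[`, "", 2)
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped from ", path)
    a <- a[!self]; b <- b[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    message(sum(dup), " duplicate unordered pair(s) collapsed")
  data.frame(gene_a = lo[!dup], gene_b = hi[!dup])
}

#' Read a gene set (one id per line)
#'
#' @param path Path to the file; \code{#} comments and blank lines skipped.
#' @param name Optional set name; defaults to the file basename.
#' @return character vector of unique gene ids, with a \code{name} attribute.
#' @export
readGeneSet <- function(path, name = NULL) {
  ids <- trimws(readLines(path, encoding = "UTF-8"))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  ids <- unique(ids)
  attr(ids, "name") <- if (is.null(name)) basename(path) else name
  ids
}

#' Dichotomize time-to-metastasis into a binary phenotype
#'
#' Samples with an observed event at or before \code{horizon} years get
#' status 1; samples followed beyond the horizon (with or without a later
#' event) get status 0; event-free samples censored before the horizon carry
#' no usable label and are abandoned.
#'
#' @param clin data.frame with \code{sample_id}, \code{time}, \code{event}.
#' @param horizon Horizon in years (default 5).
#' @return List with \code{sample_ids}, binary \code{status} (aligned),
#'   \code{abandoned} (excluded sample ids) and \code{horizon}.
#' @examples
#' clin <- data.frame(sample_id = c("a", "b", "c"),
#'                    time = c(3, 7, 3), event = c(1, 1, 0))
#' dichotomizePhenotype(clin)
#' @export
dichotomizePhenotype <- function(clin, horizon = 5) {
  stopifnot(horizon > 0)
  early_event <- clin$event == 1 & clin$time <= horizon
  past_horizon <- clin$time > horizon
  drop <- clin$event == 0 & clin$time <= horizon
  status <- ifelse(early_event, 1L, ifelse(past_horizon, 0L, NA_integer_))
  keep <- !drop
  if (!any(keep)) stop("no samples retained after dichotomization")
  list(sample_ids = clin$sample_id[keep],
       status = status[keep],
       abandoned = clin$sample_id[!keep],
       horizon = horizon)
}

#' Median-binarize an expression matrix
#'
#' Per gene, values strictly below the gene's median across all samples
#' become 0, values at or above it become 1. Constant genes yield an all-1
#' row and are flagged with a warning.
#'
#' @param expr Numeric genes x samples matrix.
#' @return Integer matrix of the same shape with values in \{0, 1\}.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4))
#' colnames(m) <- paste0("s", 1:4)
#' binarizeExpression(m)  # 0 0 1 1
#' @export
binarizeExpression <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  med <- apply(expr, 1, stats::median)
  out <- (expr >= med) * 1L
  constant <- apply(expr, 1, function(v) all(v == v[1]))
  if (any(constant))
    warning(sum(constant), " constant gene(s) binarized to all-1: ",
            paste(utils::head(rownames(expr)[constant], 5), collapse = ", "))
  storage.mode(out) <- "integer"
  out
}

#' Read a packaged signature table
#'
#' Parses a tab-delimited signature file with columns gene id, gene name
#' (optional), Cox beta, Cox p-value and stability into a
#' \linkS4class{GeneSignature}. The packaged hub-based and pseudo signature
#' tables ship in \code{inst/extdata} in this format.
#'
#' @param path Path to the signature file.
#' @return A \linkS4class{GeneSignature}.
#' @examples
#' f <- system.file("extdata", "hub_signature.tsv", package = "depnet")
#' readSignature(f)
#' @export
readSignature <- function(path) {
  d <- utils::read.delim(path, comment.char = "#",
                         colClasses = "character")
  names(d) <- tolower(names(d))
  id_col <- intersect(c("gene_id", "gene.id"), names(d))[1]
  beta_col <- intersect(c("cox_beta", "cox.beta"), names(d))[1]
  p_col <- intersect(c("cox_p", "cox_p_value", "cox.p.value"), names(d))[1]
  if (is.na(id_col) || is.na(beta_col) || is.na(p_col) ||
      !"stability" %in% names(d))
    stop("signature file must have gene id, cox beta, cox p and stability ",
         "columns: ", path)
  newSignature(data.frame(gene_id = d[[id_col]],
                          cox_beta = as.numeric(d[[beta_col]]),
                          cox_p = as.numeric(d[[p_col]]),
                          stability = as.numeric(d$stability)))
}

#' Write a signature table
#' @param sig A \linkS4class{GeneSignature}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSignature <- function(sig, path) {
  utils::write.table(signatureGenes(sig), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
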