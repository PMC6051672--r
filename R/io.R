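# Conditions accepted in sample metadata. Library and starter samples precede
# the control/treatment split and are labelled "shared".
.conditions <- c("control", "treatment", "shared")

#' Build a site key
#'
#' Insertion sites are identified by (replicon, 1-based position, strand).
#' Strand is recorded but ignored when assigning sites to genes.
#'
#' @param replicon,position,strand vectors of equal length
#' @return character vector of keys
#' @export
site_key <- function(replicon, position, strand) {
  paste(replicon, position, strand, sep = ":")
}

#' Construct a per-sample insertion count container
#'
#' @param counts data.frame with columns `replicon`, `position` (1-based),
#'   `strand` (`+`/`-`) and `count` (non-negative integers); one row per site.
#' @param sample_id sample label
#' @param condition one of `"control"`, `"treatment"`, `"shared"` (library and
#'   starter samples, which precede the split, are `"shared"`)
#' @param growth_period integer sample code: 0 = library, 1 = starter,
#'   2..4 = end of growth periods 1..3
#' @param replicate replicate index (>= 1)
#' @return object of class `sample_counts` with `total_reads` computed
#' @export
sample_counts <- function(counts, sample_id, condition, growth_period,
                          replicate = 1L) {
  required <- c("replicon", "position", "strand", "count")
  if (!all(required %in% names(counts))) {
    stop("counts must have columns: ", paste(required, collapse = ", "))
  }
  counts <- counts[required]
  counts$position <- as.integer(counts$position)
  counts$count <- as.numeric(counts$count)
  if (any(counts$position <= 0)) stop("insertion positions must be positive")
  if (any(counts$count < 0)) stop("read counts must be non-negative")
  if (!all(counts$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  keys <- site_key(counts$replicon, counts$position, counts$strand)
  if (anyDuplicated(keys)) {
    stop("duplicate site rows in count table: ",
         keys[which(duplicated(keys))[1L]])
  }
  condition <- match.arg(condition, .conditions)
  growth_period <- as.integer(growth_period)
  if (growth_period < 0L || growth_period > 4L) {
    stop("growth_period sample code must be in 0..4")
  }
  if (growth_period <= 1L && condition != "shared") {
    stop("library/starter samples (growth_period 0 or 1) must be 'shared'")
  }
  if (growth_period >= 2L && condition == "shared") {
    stop("post-split samples must be 'control' or 'treatment'")
  }
  structure(
    list(sample_id = as.character(sample_id), condition = condition,
         growth_period = growth_period, replicate = as.integer(replicate),
         counts = counts, total_reads = sum(counts$count)),
    class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat(sprintf("<sample_counts> %s [%s, period code %d, rep %d]: %d sites, %s reads\n",
              x$sample_id, x$condition, x$growth_period, x$replicate,
              nrow(x$counts), format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Read a per-sample insertion count table
#'
#' Expects a UTF-8 TSV with header `replicon  position  strand  count`;
#' lines starting with `#` are comments. `total_reads` is computed on read and
#' duplicate sites or negative counts are rejected.
#'
#' @inheritParams sample_counts
#' @param path file path
#' @return `sample_counts`
#' @export
read_count_table <- function(path, sample_id = basename(path),
                             condition = "shared", growth_period = 0L,
                             replicate = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c(replicon = "character",
                                         strand = "character"))
  sample_counts(df, sample_id, condition, growth_period, replicate)
}

#' Write a count table (TSV round-trip partner of [read_count_table()])
#'
#' Rows are written sorted by (replicon, position, strand) so output is
#' deterministic.
#'
#' @param x `sample_counts`
#' @param path output path
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "sample_counts"))
  df <- x$counts
  df <- df[order(df$replicon, df$position, df$strand), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene features from a GFF3 annotation
#'
#' Coordinates are kept 1-based inclusive per the GFF3 standard. Feature
#' identity comes from the `ID` attribute (falling back to `locus_tag`), the
#' display name from `Name` if present.
#'
#' @param path GFF3 file
#' @param feature_type feature types to keep (default `"gene"`, with `"CDS"`
#'   used when no gene records exist)
#' @return data.frame with columns gene_id, name, replicon, start, end, strand
#' @export
read_gff3 <- function(path, feature_type = c("gene", "CDS")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L) {
      stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                   i, length(fields)))
    }
    s <- suppressWarnings(as.numeric(fields[4L]))
    e <- suppressWarnings(as.numeric(fields[5L]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("malformed GFF3 line %d: non-numeric coordinates", i))
    }
    if (e < s) {
      stop(sprintf("GFF3 line %d: end (%s) < start (%s)", i, fields[5L], fields[4L]))
    }
  }
  if (length(body) == 0L) {
    warning("empty GFF3 annotation: ", path)
    return(data.frame(gene_id = character(), name = character(),
                      replicon = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% feature_type
  if (any(as.character(gr$type) == feature_type[1L])) {
    keep <- as.character(gr$type) == feature_type[1L]
  }
  gr <- gr[keep]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$locus_tag
  if (is.null(ids) || anyNA(ids)) {
    stop("GFF3 feature without an ID attribute in ", path)
  }
  nm <- gr$Name
  if (is.null(nm)) nm <- ids
  nm[is.na(nm)] <- ids[is.na(nm)]
  out <- data.frame(
    gene_id = as.character(ids), name = as.character(nm),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         out$gene_id[which(duplicated(out$gene_id))[1L]])
  }
  out[order(out$replicon, out$start), , drop = FALSE]
}

#' Read viable-cell growth records
#'
#' TSV with columns `condition`, `growth_period` (1..3), `replicate`, `N0`,
#' `Nf`. N0 and Nf are viable-cell counts at the start and end of one growth
#' period and must be positive.
#'
#' @param path file path
#' @return validated data.frame
#' @export
read_viable_counts <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("condition", "growth_period", "replicate", "N0", "Nf")
  if (!all(required %in% names(df))) {
    stop("viable-count table needs columns: ", paste(required, collapse = ", "))
  }
  if (any(df$N0 <= 0) || any(df$Nf <= 0)) {
    stop("viable counts N0 and Nf must be positive")
  }
  if (!all(df$condition %in% c("control", "treatment"))) {
    stop("viable-count condition must be 'control' or 'treatment'")
  }
  df$growth_period <- as.integer(df$growth_period)
  df$replicate <- as.integer(df$replicate)
  df[required]
}

#' @rdname read_viable_counts
#' @param x data.frame of growth records
#' @export
write_viable_counts <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-length table
#'
#' TSV with columns `strain`, `condition`, `timepoint`, `length_um`
#' (micrometres, positive).
#'
#' @param path file path
#' @return validated data.frame
#' @export
read_length_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("strain", "condition", "timepoint", "length_um")
  if (!all(required %in% names(df))) {
    stop("length table needs columns: ", paste(required, collapse = ", "))
  }
  if (any(df$length_um <= 0)) stop("cell lengths must be positive")
  df[required]
}

#' Read a spectral-count matrix
#'
#' TSV with a `protein_id` column followed by one numeric column per sample.
#' Every protein must be present in every sample (no ragged rows, enforced by
#' the rectangular format plus an NA check).
#'
#' @param path file path
#' @return numeric matrix, proteins in rows, samples in columns
#' @export
read_spectral_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1L] != "protein_id") {
    stop("first column of a spectral table must be 'protein_id'")
  }
  if (anyDuplicated(df$protein_id)) stop("duplicate protein_id rows")
  m <- as.matrix(df[-1L])
  if (!is.numeric(m) || anyNA(m)) {
    stop("spectral matrix must be complete and numeric (a sample is missing a protein value)")
  }
  if (any(m < 0)) stop("spectral counts must be non-negative")
  rownames(m) <- df$protein_id
  m
}

#' @rdname read_spectral_table
#' @param x matrix with protein rownames
#' @export
write_spectral_table <- function(x, path) {
  df <- data.frame(protein_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene-level fitness table
#'
#' Columns `gene_id`, `growth_period`, `n_insertions`, `mean_relative_fitness`,
#' `ci95_low`, `ci95_high`, `p_value`, `p_adj`, sorted ascending by mean
#' relative fitness (candidate-list presentation order).
#'
#' @param x gene table as returned by [gene_fitness()]
#' @param path output path
#' @export
write_gene_table <- function(x, path) {
  required <- c("gene_id", "growth_period", "n_insertions",
                "mean_relative_fitness", "ci95_low", "ci95_high",
                "p_value", "p_adj")
  if (!all(required %in% names(x))) {
    stop("gene table needs columns: ", paste(required, collapse = ", "))
  }
  if (any(x$n_insertions <= 0)) {
    stop("gene records with no contributing insertions must be filtered upstream")
  }
  x <- x[order(x$mean_relative_fitness, x$p_adj, x$gene_id), required]
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a run manifest
#'
#' The manifest is a YAML file tying sample count-table files to their
#' (condition, growth-period, replicate) coordinates, plus the annotation and
#' viable-count files. All paths are interpreted relative to the manifest's
#' directory.
#'
#' @param path manifest YAML
#' @return a `tnseq_experiment` list with elements `samples` (list of
#'   `sample_counts`), `growth` (viable-count data.frame) and `annotation`
#'   (gene data.frame, if an annotation file is listed)
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (startsWith(p, "/")) p else file.path(base, p)
  if (is.null(m$samples)) stop("manifest has no 'samples' entry")
  samples <- lapply(m$samples, function(s) {
    read_count_table(rel(s$file), sample_id = s$sample_id %||% basename(s$file),
                     condition = s$condition, growth_period = s$growth_period,
                     replicate = s$replicate %||% 1L)
  })
  growth <- if (!is.null(m$viable_counts)) read_viable_counts(rel(m$viable_counts))
  annotation <- if (!is.null(m$annotation)) read_gff3(rel(m$annotation))
  structure(list(samples = samples, growth = growth, annotation = annotation),
            class = "tnseq_experiment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tnseq_experiment <- function(x, ...) {
  cat(sprintf("<tnseq_experiment> %d samples, %s growth records, %s genes\n",
              length(x$samples),
              if (is.null(x$growth)) "no" else nrow(x$growth),
              if (is.null(x$annotation)) "no" else nrow(x$annotation)))
  invisible(x)
}
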