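#' Read a Bismark-style coverage file
#'
#' Parses the six-column tab-separated coverage format produced by
#' `bismark2bedGraph`/`coverage2cytosine`: chromosome, start (1-based),
#' end, methylation percentage, methylated count, unmethylated count.
#' The sequence context is not encoded in the format and is supplied by
#' the caller (conventionally from the file name).
#'
#' @param path Path to the coverage file. Files ending in `.gz` are
#'   decompressed transparently.
#' @param context Sequence context of the calls in the file: one of
#'   `"CpG"`, `"CHG"`, `"CHH"`.
#' @return A CpG call table: a `data.frame` with columns `chrom`,
#'   `pos` (1-based), `context`, `meth`, `unmeth`.
#' @details Each line is validated: counts must be non-negative integers
#'   with `meth + unmeth >= 1`, and the percentage column must agree with
#'   `100 * meth / (meth + unmeth)` to within rounding (0.5 percentage
#'   points). Malformed lines abort the read with the offending line
#'   number.
#' @export
read_coverage_file <- function(path, context = c("CpG", "CHG", "CHH")) {
  context <- match.arg(context)
  if (!file.exists(path)) stop("coverage file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L) return(empty_calls())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1L]
    stop("malformed coverage line ", bad, " in ", path,
         ": expected 6 tab-separated fields, got ", nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  pos    <- suppressWarnings(as.integer(m[, 2L]))
  pct    <- suppressWarnings(as.numeric(m[, 4L]))
  meth   <- suppressWarnings(as.integer(m[, 5L]))
  unmeth <- suppressWarnings(as.integer(m[, 6L]))
  bad <- which(is.na(pos) | is.na(pct) | is.na(meth) | is.na(unmeth) |
                 meth < 0L | unmeth < 0L | meth + unmeth < 1L)
  if (length(bad)) {
    stop("malformed coverage line ", bad[1L], " in ", path,
         ": non-numeric or invalid counts")
  }
  implied <- 100 * meth / (meth + unmeth)
  off <- which(abs(implied - pct) > 0.5)
  if (length(off)) {
    stop("coverage line ", off[1L], " in ", path,
         ": percentage ", pct[off[1L]], " inconsistent with counts ",
         meth[off[1L]], "/", meth[off[1L]] + unmeth[off[1L]],
         " (implies ", round(implied[off[1L]], 2), ")")
  }
  cpg_calls(chrom = m[, 1L], pos = pos, context = context,
            meth = meth, unmeth = unmeth)
}

#' Write a CpG call table as a Bismark-style coverage file
#'
#' @param calls A CpG call table (see [read_coverage_file()]).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(calls, path) {
  calls <- validate_calls(calls)
  pct <- ifelse(calls$meth + calls$unmeth > 0,
                100 * calls$meth / (calls$meth + calls$unmeth), 0)
  out <- data.frame(calls$chrom, calls$pos, calls$pos,
                    format(pct, trim = TRUE, digits = 7),
                    calls$meth, calls$unmeth)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a CpG call table
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param context Sequence context per record (`"CpG"`, `"CHG"`, `"CHH"`).
#' @param meth,unmeth Methylated / unmethylated call counts.
#' @return A validated `data.frame` with those five columns.
#' @export
cpg_calls <- function(chrom, pos, context = "CpG", meth, unmeth) {
  validate_calls(data.frame(chrom = as.character(chrom),
                            pos = as.integer(pos),
                            context = as.character(context),
                            meth = as.integer(meth),
                            unmeth = as.integer(unmeth),
                            stringsAsFactors = FALSE))
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), context = character(),
             meth = integer(), unmeth = integer(), stringsAsFactors = FALSE)
}

validate_calls <- function(calls) {
  req <- c("chrom", "pos", "context", "meth", "unmeth")
  if (!is.data.frame(calls) || !all(req %in% names(calls)))
    stop("a call table needs columns: ", paste(req, collapse = ", "))
  if (nrow(calls) == 0L) return(calls[req])
  if (any(calls$meth < 0L) || any(calls$unmeth < 0L))
    stop("negative call counts")
  if (any(calls$meth + calls$unmeth < 1L))
    stop("records must carry at least one call")
  if (!all(calls$context %in% c("CpG", "CHG", "CHH")))
    stop("context must be one of CpG, CHG, CHH")
  if (anyDuplicated(calls[c("chrom", "pos", "context")]))
    stop("duplicate positions within a (chromosome, context)")
  calls[req]
}

#' Read a BED interval file into a domain set
#'
#' Intervals use BED conventions: 0-based start, exclusive end. Column 4,
#' when present, is the interval name and column 5 the class label; when a
#' `class` argument is given it overrides column 5.
#'
#' @param path Path to a tab-separated BED file (3-5 columns, no header).
#' @param class Optional class label applied to all intervals.
#' @return A domain set: `data.frame` with `chrom`, `start`, `end`,
#'   `name`, `class`.
#' @export
read_bed <- function(path, class = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("BED file needs at least 3 columns: ", path)
  raw[[1]] <- as.character(raw[[1]])
  nm <- if (ncol(raw) >= 4) as.character(raw[[4]]) else
    paste0(raw[[1]], ":", raw[[2]], "-", raw[[3]])
  cl <- if (!is.null(class)) class else if (ncol(raw) >= 5) as.character(raw[[5]]) else NA_character_
  domain_set(chrom = raw[[1]], start = raw[[2]], end = raw[[3]],
             name = nm, class = cl)
}

#' Write a domain set as a BED file
#'
#' @param domains A domain set (`chrom`, `start`, `end`, `name`, `class`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(domains, path) {
  out <- domains[c("chrom", "start", "end", "name", "class")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a domain set of labelled genomic intervals
#'
#' @param chrom,start,end Interval coordinates (BED: 0-based half-open).
#' @param name Interval identifiers (unique).
#' @param class Class labels, e.g. `hyper`, `hypo`, `inter`,
#'   `gdmr_maternal`, `gdmr_paternal`, `secondary_dmr`, `gene_body`,
#'   `x_cgi`.
#' @return A validated `data.frame`.
#' @export
domain_set <- function(chrom, start, end, name = NULL, class = NA_character_) {
  if (is.null(name)) name <- paste0(chrom, ":", start, "-", end)
  d <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), name = as.character(name),
                  class = as.character(class), stringsAsFactors = FALSE)
  if (any(d$start >= d$end)) stop("intervals must satisfy start < end")
  if (anyDuplicated(d$name)) stop("interval names must be unique")
  tiling <- d[d$class %in% c("hyper", "hypo", "inter"), ]
  if (nrow(tiling) > 1L) {
    gr <- domains_to_granges(tiling)
    if (sum(GenomicRanges::width(GenomicRanges::reduce(gr))) !=
          sum(GenomicRanges::width(gr)))
      stop("hyper/hypo/inter tiling intervals must not overlap")
  }
  d
}

# BED half-open 0-based -> GRanges (1-based closed). The single place the
# coordinate conversion happens.
domains_to_granges <- function(domains) {
  GenomicRanges::GRanges(domains$chrom,
                         IRanges::IRanges(start = domains$start + 1L,
                                          end = domains$end))
}

calls_to_granges <- function(calls) {
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(start = calls$pos, width = 1L))
}

#' Read a tab-separated genes-by-cells count matrix
#'
#' @param path Tab-separated file with gene identifiers in the first
#'   column and one column per cell (header row of cell identifiers).
#' @return An integer matrix, genes in rows.
#' @export
read_count_matrix <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           row.names = 1, check.names = FALSE)
  m <- as.matrix(raw)
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) stop("counts must be non-negative")
  m
}

#' Write a genes-by-cells count matrix
#'
#' @param counts Integer matrix with gene row names and cell column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell samplesheet
#'
#' A tab-separated table with header; expected columns `cell_id`, `path`,
#' `age_group` and optionally `mapping_efficiency` (percent, from the
#' aligner's log; used by QC only when present).
#'
#' @param path Path to the samplesheet.
#' @return A `data.frame`.
#' @export
read_samplesheet <- function(path) {
  ss <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  req <- c("cell_id", "path", "age_group")
  if (!all(req %in% names(ss)))
    stop("samplesheet needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(ss$cell_id)) stop("duplicate cell_id in samplesheet")
  ss
}
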