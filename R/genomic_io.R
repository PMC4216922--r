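# Internal coordinates are 0-based half-open everywhere (BED convention);
# 1-based inclusive TSV input is converted at the boundary.

STRANDS <- c("+", "-", ".")

#' Construct a set of genomic intervals
#'
#' Intervals are stored 0-based half-open, the convention used internally
#' throughout the package.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param strand strand symbols among `"+"`, `"-"`, `"."`.
#' @return A data frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1L]
    stop(sprintf("invalid interval at row %d: start (%s) >= end (%s)",
                 bad, df$start[bad], df$end[bad]))
  }
  if (!all(df$strand %in% STRANDS)) stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

#' Build gene models from coordinates
#'
#' The TSS of a plus-strand gene is its start; for a minus-strand gene it is
#' `end - 1` (the last base), symmetrically. `exons` and the `thick`
#' (CDS) span are optional and only needed for feature-map construction.
#'
#' @param gene_id unique gene identifiers.
#' @param chrom,start,end,strand gene coordinates, 0-based half-open.
#' @param exons optional list (one element per gene) of two-column matrices
#'   of exon `start`,`end` coordinates nested within the gene.
#' @param thick_start,thick_end optional CDS span per gene (0-based
#'   half-open); `NA` for non-coding models.
#' @return A data frame of class `gene_models` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `tss`, `tes` and (optionally) an
#'   `exons` list column plus `thick_start`/`thick_end`.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand,
                        exons = NULL, thick_start = NULL, thick_end = NULL) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  }
  df <- genomic_intervals(chrom, start, end, strand)
  if (any(df$strand == ".")) stop("gene models require a '+' or '-' strand")
  df <- data.frame(gene_id = gene_id, df, stringsAsFactors = FALSE)
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df$tes <- ifelse(df$strand == "+", df$end - 1, df$start)
  if (!is.null(exons)) {
    stopifnot(length(exons) == nrow(df))
    for (i in seq_along(exons)) {
      ex <- exons[[i]]
      if (is.null(ex)) next
      if (any(ex[, 1] < df$start[i]) || any(ex[, 2] > df$end[i])) {
        stop("exons of gene ", gene_id[i], " extend beyond the gene interval")
      }
      o <- order(ex[, 1])
      ex <- ex[o, , drop = FALSE]
      if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])) {
        stop("overlapping exons in gene ", gene_id[i])
      }
      exons[[i]] <- ex
    }
    df$exons <- I(exons)
  }
  if (!is.null(thick_start)) {
    df$thick_start <- as.numeric(thick_start)
    df$thick_end <- as.numeric(thick_end)
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

split_fields <- function(lines, n_min, what) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < n_min)
  if (length(bad)) {
    stop(sprintf("malformed %s line %d: expected >= %d tab-separated fields",
                 what, bad[1L], n_min))
  }
  fields
}

num_field <- function(fields, i, lines_what) {
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  if (anyNA(x)) {
    stop(sprintf("malformed %s line %d: field %d is not numeric",
                 lines_what, which(is.na(x))[1L], i))
  }
  x
}

#' Read gene models from BED or TSV
#'
#' BED input (6 or 12 columns) is 0-based half-open. TSV input must carry a
#' header with columns `gene_id`, `chrom`, `start`, `end`, `strand` and uses
#' 1-based inclusive coordinates; both map to the same internal interval.
#' BED12 block and thick fields populate exon and CDS structure.
#'
#' @param path input file.
#' @param format `"bed"` or `"tsv"`.
#' @return A `gene_models` data frame, input order preserved.
#' @export
load_gene_models <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(tab))) {
      stop("TSV gene table must have header columns: ",
           paste(need, collapse = ", "))
    }
    # 1-based inclusive -> 0-based half-open
    return(gene_models(tab$gene_id, tab$chrom, tab$start - 1, tab$end,
                       tab$strand))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty BED file: ", path)
  fields <- split_fields(lines, 6L, "BED")
  nf <- vapply(fields, length, 1L)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- num_field(fields, 2L, "BED")
  end <- num_field(fields, 3L, "BED")
  name <- vapply(fields, `[[`, "", 4L)
  strand <- vapply(fields, `[[`, "", 6L)
  exons <- NULL
  thick_s <- NULL
  thick_e <- NULL
  if (all(nf >= 12L)) {
    thick_s <- num_field(fields, 7L, "BED")
    thick_e <- num_field(fields, 8L, "BED")
    n_blocks <- num_field(fields, 10L, "BED")
    exons <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      sizes <- as.numeric(strsplit(vapply(fields[i], `[[`, "", 11L), ",")[[1]])
      starts <- as.numeric(strsplit(vapply(fields[i], `[[`, "", 12L), ",")[[1]])
      if (length(sizes) != n_blocks[i] || length(starts) != n_blocks[i]) {
        stop(sprintf("malformed BED line %d: block count mismatch", i))
      }
      exons[[i]] <- cbind(start = start[i] + starts,
                          end = start[i] + starts + sizes)
    }
  }
  gene_models(name, chrom, start, end, strand, exons = exons,
              thick_start = thick_s, thick_end = thick_e)
}

#' Write gene models as BED
#'
#' Emits BED12 when exon structure is present, BED6 otherwise; round-trips
#' through [load_gene_models()].
#'
#' @param genes a `gene_models` data frame.
#' @param path output file.
#' @export
write_gene_models <- function(genes, path) {
  if (!is.null(genes$exons)) {
    lines <- vapply(seq_len(nrow(genes)), function(i) {
      ex <- genes$exons[[i]]
      ts <- if (!is.null(genes$thick_start)) genes$thick_start[i] else genes$start[i]
      te <- if (!is.null(genes$thick_end)) genes$thick_end[i] else genes$start[i]
      paste(genes$chrom[i], genes$start[i], genes$end[i], genes$gene_id[i],
            0, genes$strand[i], ts, te, "0",
            nrow(ex),
            paste0(paste(ex[, 2] - ex[, 1], collapse = ","), ","),
            paste0(paste(ex[, 1] - genes$start[i], collapse = ","), ","),
            sep = "\t")
    }, "")
  } else {
    lines <- paste(genes$chrom, genes$start, genes$end, genes$gene_id, 0,
                   genes$strand, sep = "\t")
  }
  writeLines(lines, path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path file with chromosome name and length per line.
#' @return Named numeric vector of chromosome lengths.
#' @export
load_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "size"),
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$size), tab$chrom)
}

#' Construct a coverage track
#'
#' A coverage track stores raw tag counts per fixed-width bin (per base when
#' `bin = 1`) for each chromosome, so that `library_size` equals the sum of
#' all values. Binned quantification of windows whose edges do not align
#' with bin edges is approximate to within one bin.
#'
#' @param values named list of non-negative numeric vectors, one per
#'   chromosome, counts per bin.
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @param bin bin width in bp.
#' @param label sample name.
#' @param condition experimental condition, one of `"ctrl"`, `"aniso"`,
#'   `"aniso+H89"`, `"H89"`, or `NA`.
#' @param library_size total mapped tags; defaults to the sum of all
#'   values, the appropriate choice when the track covers the whole
#'   genome. Override only when tags map outside the covered region.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, chrom_sizes, bin = 1L, label = "",
                           condition = NA_character_, library_size = NULL) {
  stopifnot(is.list(values), !is.null(names(values)),
            all(names(values) %in% names(chrom_sizes)))
  for (ch in names(values)) {
    v <- values[[ch]]
    if (any(v < 0)) stop("negative coverage value on ", ch)
    nb <- ceiling(chrom_sizes[[ch]] / bin)
    if (length(v) != nb) {
      stop(sprintf("chromosome %s: %d bins supplied, %d expected", ch,
                   length(v), nb))
    }
  }
  if (is.null(library_size)) library_size <- sum(vapply(values, sum, 0))
  structure(list(values = values,
                 chrom_sizes = chrom_sizes[names(values)],
                 bin = as.integer(bin),
                 library_size = library_size,
                 label = label, condition = condition),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track '%s' (%s): %d chromosome(s), bin %d bp, %.0f tags\n",
              x$label, x$condition, length(x$values), x$bin, x$library_size))
  invisible(x)
}

#' Read a bedGraph file into a coverage track
#'
#' Uncovered bases are zero; overlapping intervals are rejected rather than
#' summed, and intervals beyond the declared chromosome end are an error.
#'
#' @param path bedGraph file (track lines not supported).
#' @param chrom_sizes named vector of chromosome lengths, or a path to a
#'   chrom.sizes file.
#' @param bin target bin width of the returned track.
#' @inheritParams coverage_track
#' @return A `coverage_track`.
#' @export
load_coverage <- function(path, chrom_sizes, bin = 1L, label = basename(path),
                          condition = NA_character_) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L) {
    chrom_sizes <- load_chrom_sizes(chrom_sizes)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  values <- lapply(chrom_sizes, function(sz) numeric(ceiling(sz / bin)))
  if (length(lines)) {
    fields <- split_fields(lines, 4L, "bedGraph")
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- num_field(fields, 2L, "bedGraph")
    end <- num_field(fields, 3L, "bedGraph")
    val <- num_field(fields, 4L, "bedGraph")
    unknown <- !(chrom %in% names(chrom_sizes))
    if (any(unknown)) {
      stop(sprintf("bedGraph line %d: unknown chromosome '%s'",
                   which(unknown)[1L], chrom[which(unknown)[1L]]))
    }
    if (any(start < 0) || any(start >= end)) {
      stop(sprintf("bedGraph line %d: invalid interval",
                   which(start < 0 | start >= end)[1L]))
    }
    over <- end > chrom_sizes[chrom]
    if (any(over)) {
      stop(sprintf("bedGraph line %d: interval beyond end of %s",
                   which(over)[1L], chrom[which(over)[1L]]))
    }
    if (any(val < 0)) {
      stop(sprintf("bedGraph line %d: negative value", which(val < 0)[1L]))
    }
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      o <- i[order(start[i])]
      if (length(o) > 1 && any(start[o][-1] < end[o][-length(o)])) {
        stop("overlapping bedGraph intervals on ", ch)
      }
      # per-base tag density 'val' accumulated into bins by bp overlap
      for (j in o) {
        values[[ch]] <- add_window_counts(values[[ch]], start[j], end[j],
                                          val[j], bin)
      }
    }
  }
  coverage_track(values, chrom_sizes, bin = bin, label = label,
                 condition = condition)
}

# Returns `v` with `density` tags/bp added over [start, end), split across
# bins by bp overlap.
add_window_counts <- function(v, start, end, density, bin) {
  b1 <- floor(start / bin) + 1L
  b2 <- ceiling(end / bin)
  if (b1 == b2) {
    v[b1] <- v[b1] + density * (end - start)
  } else {
    v[b1] <- v[b1] + density * (b1 * bin - start)
    v[b2] <- v[b2] + density * (end - (b2 - 1) * bin)
    if (b2 - b1 > 1) {
      mid <- (b1 + 1L):(b2 - 1L)
      v[mid] <- v[mid] + density * bin
    }
  }
  v
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-valued bins are merged; zero runs are omitted. The written
#' value is the per-base tag density of the bin, so that
#' `load_coverage(write_coverage(x))` reproduces `x` exactly when re-read at
#' the same bin width.
#'
#' @param track a `coverage_track`.
#' @param path output file.
#' @export
write_coverage <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    sz <- track$chrom_sizes[[ch]]
    widths <- rep(track$bin, length(v))
    if (length(v)) widths[length(v)] <- sz - (length(v) - 1) * track$bin
    dens <- v / widths
    r <- rle(dens)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0, ends_bin[-length(ends_bin)])
    keep <- r$values != 0
    if (any(keep)) {
      s <- starts_bin[keep] * track$bin
      e <- pmin(ends_bin[keep] * track$bin, sz)
      writeLines(paste(ch, format(s, scientific = FALSE, trim = TRUE),
                       format(e, scientific = FALSE, trim = TRUE),
                       format(r$values[keep], digits = 15, trim = TRUE),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a record table as TSV
#'
#' Tab-separated with header, deterministic column order, no quoting; pairs
#' with [read_record_table()] as an identity on valid records.
#'
#' @param records a data frame.
#' @param path output file.
#' @export
write_record_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  drop <- vapply(records, is.list, TRUE)
  utils::write.table(records[, !drop, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_record_table()]
#'
#' @param path input file.
#' @return A data frame.
#' @export
read_record_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
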