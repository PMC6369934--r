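#' Read a SNP count matrix
#'
#' Two on-disk formats are supported. The native TSV dialect has a header
#' \code{chrom pos locus_id ref alt <pop>:ref <pop>:alt ...}, is
#' tab-separated and permits \code{#} comment lines. The popoolation2-style
#' sync format has columns \code{chrom pos refbase} followed by one
#' \code{A:T:C:G:N:del} count column per population; sites are reduced to
#' the two most frequent nucleotides over all pools, and a site is skipped
#' with a warning when a third allele exceeds 10\% of its total depth.
#'
#' @param path file path.
#' @param fmt \code{"tsv"} or \code{"sync"}.
#' @param populations a \code{\link{population_spec}} table, in file column
#'   order (required for sync; checked against the header for tsv).
#' @param layout a \code{\link{genome_layout}} table.
#' @return a \code{\link{snp_matrix}}.
#' @export
read_snp_matrix <- function(path, fmt = c("tsv", "sync"), populations, layout) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "tsv") read_snp_tsv(path, populations, layout)
  else read_snp_sync(path, populations, layout)
}

read_snp_tsv <- function(path, populations, layout) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "locus_id", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("malformed TSV header; expected columns ", paste(need, collapse = ", "))
  }
  ref_cols <- paste0(populations$name, ":ref")
  alt_cols <- paste0(populations$name, ":alt")
  if (!all(c(ref_cols, alt_cols) %in% names(df))) {
    stop("population count columns do not match the population config")
  }
  snp_matrix(df[need], as.matrix(df[ref_cols]), as.matrix(df[alt_cols]),
             populations, layout)
}

read_snp_sync <- function(path, populations, layout) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  npop <- nrow(populations)
  nc <- lengths(fields)
  bad <- which(nc != 3 + npop)
  if (length(bad)) {
    stop(sprintf("sync parse error at line %d: %d columns, expected %d",
                 bad[1], nc[bad[1]], 3 + npop))
  }
  nts <- c("A", "T", "C", "G")
  n <- length(fields)
  chrom <- vapply(fields, `[`, "", 1L)
  pos <- as.numeric(vapply(fields, `[`, "", 2L))
  if (anyNA(pos)) {
    stop("sync parse error at line ", which(is.na(pos))[1], ": bad position")
  }
  refbase <- toupper(vapply(fields, `[`, "", 3L))
  # counts[site, nucleotide, pop]
  counts <- array(0, dim = c(n, 4L, npop))
  for (j in seq_len(npop)) {
    col <- vapply(fields, `[`, "", 3L + j)
    parts <- strsplit(col, ":", fixed = TRUE)
    if (any(lengths(parts) != 6L)) {
      stop("sync parse error at line ", which(lengths(parts) != 6L)[1],
           ": count field is not A:T:C:G:N:del")
    }
    pm <- matrix(as.numeric(unlist(parts)), ncol = 6L, byrow = TRUE)
    counts[, , j] <- pm[, 1:4, drop = FALSE]
  }
  tot <- apply(counts, c(1, 2), sum)            # per-site per-nucleotide
  ord <- apply(tot, 1L, order, decreasing = TRUE)  # 4 x n
  major1 <- ord[1L, ]
  major2 <- ord[2L, ]
  third <- ord[3L, ]
  depth <- rowSums(tot)
  tri <- depth > 0 & tot[cbind(seq_len(n), third)] > 0.10 * depth
  if (any(tri)) {
    warning(sum(tri), " site(s) skipped: third allele exceeds 10% of depth ",
            "(first at line ", which(tri)[1], ")")
  }
  keep <- !tri & tot[cbind(seq_len(n), major2)] > 0
  # honour the file's reference base when it is one of the two alleles
  ref_i <- major1
  alt_i <- major2
  swap <- nts[major2] == refbase
  ref_i[swap] <- major2[swap]
  alt_i[swap] <- major1[swap]
  ref_counts <- matrix(0, n, npop)
  alt_counts <- matrix(0, n, npop)
  for (j in seq_len(npop)) {
    ref_counts[, j] <- counts[cbind(seq_len(n), ref_i, j)]
    alt_counts[, j] <- counts[cbind(seq_len(n), alt_i, j)]
  }
  snps <- data.frame(chrom = chrom, pos = pos,
                     locus_id = paste0(chrom, "_", pos),
                     ref = nts[ref_i], alt = nts[alt_i],
                     stringsAsFactors = FALSE)
  snp_matrix(snps[keep, , drop = FALSE],
             ref_counts[keep, , drop = FALSE],
             alt_counts[keep, , drop = FALSE], populations, layout)
}

#' Write a SNP count matrix
#'
#' @param m a \code{\link{snp_matrix}}.
#' @param path output file path.
#' @param fmt \code{"tsv"} (native dialect) or \code{"sync"}
#'   (popoolation2-style; RAD-locus identifiers are not representable and
#'   are regenerated as \code{chrom_pos} on re-read).
#' @return \code{path}, invisibly.
#' @export
write_snp_matrix <- function(m, path, fmt = c("tsv", "sync")) {
  fmt <- match.arg(fmt)
  if (fmt == "tsv") {
    df <- m$snps
    for (j in seq_len(nrow(m$populations))) {
      df[[paste0(m$populations$name[j], ":ref")]] <- m$ref_counts[, j]
      df[[paste0(m$populations$name[j], ":alt")]] <- m$alt_counts[, j]
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    nts <- c("A", "T", "C", "G")
    ri <- match(m$snps$ref, nts)
    ai <- match(m$snps$alt, nts)
    n <- nrow(m$snps)
    cols <- vapply(seq_len(nrow(m$populations)), function(j) {
      cm <- matrix(0, n, 6L)
      cm[cbind(seq_len(n), ri)] <- m$ref_counts[, j]
      cm[cbind(seq_len(n), ai)] <- m$alt_counts[, j]
      apply(cm, 1L, paste, collapse = ":")
    }, character(n))
    lines <- paste(m$snps$chrom, m$snps$pos, m$snps$ref,
                   apply(matrix(cols, nrow = n), 1L, paste, collapse = "\t"),
                   sep = "\t")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a population configuration (YAML or JSON)
#'
#' Expects a list of entries with fields \code{name}, \code{habitat},
#' \code{pool_size} and optional \code{group_tag}.
#'
#' @param path file path; format chosen by extension (\code{.json} vs YAML).
#' @return a \code{\link{population_spec}} table.
#' @export
read_population_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  if (!length(cfg)) stop("empty population config")
  population_spec(
    name = vapply(cfg, function(x) as.character(x$name), ""),
    habitat = vapply(cfg, function(x) as.character(x$habitat), ""),
    pool_size = vapply(cfg, function(x) as.integer(x$pool_size), 0L),
    group_tag = vapply(cfg, function(x)
      if (is.null(x$group_tag)) NA_character_ else as.character(x$group_tag), "")
  )
}

#' Read a genome layout from a two-column TSV (chrom, length)
#' @param path file path; no header, \code{#} comments allowed.
#' @return a \code{\link{genome_layout}} table.
#' @export
read_genome_layout <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  genome_layout(df[[1]], df[[2]])
}

#' Export core regions as BED (0-based, half-open)
#'
#' Internal coordinates are 1-based inclusive; BED output converts to
#' 0-based half-open intervals.
#'
#' @param regions a core-region table from \code{\link{detect_core_snps}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = paste0("core_", seq_len(nrow(regions))),
                    score = round(1000 * regions$core_afd),
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
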