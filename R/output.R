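#' Output writers and spatial-pedigree replay
#'
#' Genomic data can be written as VCF 4.2 (phased genotypes -- chromatids are
#' explicit -- with monomorphic loci omitted by default) and FASTA (two
#' sequences per individual, alleles mapped 0 -> 'A', 1 -> 'T'); nongenomic
#' individual data as CSV, GeoJSON, or point Shapefile. All writers are
#' deterministic given model state. The recorded spatial pedigree allows any
#' individual's genome to be reconstructed exactly from founder genomes and
#' stored recombination switch positions.
#'
#' @name output
NULL

#' Write genotypes to VCF 4.2
#'
#' One record per segregating locus: CHROM "1", POS = locus index (1-based),
#' REF "A", ALT "T", phased sample genotypes ("0|1" orders the two
#' chromatids). Monomorphic loci are omitted unless `include_monomorphic`.
#'
#' @param ch1,ch2 N x L chromatid matrices.
#' @param ids individual ids (column names `ind<id>`).
#' @param path output path.
#' @param include_monomorphic also write invariant loci.
#' @export
write_vcf <- function(ch1, ch2, ids, path, include_monomorphic = FALSE) {
  n <- nrow(ch1)
  if (n == 0) stop("cannot write a VCF for zero individuals")
  L <- ncol(ch1)
  tot <- colSums(ch1) + colSums(ch2)
  keep <- if (include_monomorphic) seq_len(L) else
    which(tot > 0 & tot < 2L * n)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=landgen",
           sprintf("##contig=<ID=1,length=%d>", L),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("ind", ids)), collapse = "\t"))
  rows <- character(length(keep))
  for (k in seq_along(keep)) {
    l <- keep[k]
    gt <- paste0(ch1[, l], "|", ch2[, l])
    rows[k] <- paste(c("1", l, paste0("loc", l), "A", "T", ".", "PASS", ".",
                       "GT", gt), collapse = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write genomes to FASTA
#'
#' Two sequences per individual (one per chromatid), alleles mapped
#' 0 -> 'A', 1 -> 'T'; headers carry the individual id and chromatid index.
#'
#' @inheritParams write_vcf
#' @export
write_fasta <- function(ch1, ch2, ids, path) {
  to_seq <- function(m) {
    apply(m, 1, function(r) paste(c("A", "T")[r + 1L], collapse = ""))
  }
  s1 <- to_seq(ch1); s2 <- to_seq(ch2)
  lines <- character(4L * length(ids))
  lines[seq(1, by = 4, length.out = length(ids))] <-
    paste0(">ind", ids, "_chromatid0")
  lines[seq(2, by = 4, length.out = length(ids))] <- s1
  lines[seq(3, by = 4, length.out = length(ids))] <-
    paste0(">ind", ids, "_chromatid1")
  lines[seq(4, by = 4, length.out = length(ids))] <- s2
  writeLines(lines, path)
  invisible(path)
}

#' Write individual records to CSV, GeoJSON, or Shapefile
#'
#' One row/feature per individual carrying all record fields; geometries are
#' points in landscape (or georeferenced) coordinates. The Shapefile writer
#' emits point-type .shp/.shx plus a .dbf attribute table.
#'
#' @param records tibble (e.g. from [individuals_table()]) with `x`, `y`
#'   columns.
#' @param path output path (extension added if missing for shapefile parts).
#' @param format `"csv"`, `"geojson"`, or `"shapefile"`.
#' @export
write_individuals <- function(records, path,
                              format = c("csv", "geojson", "shapefile")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else if (format == "geojson") {
    feats <- lapply(seq_len(nrow(records)), function(i) {
      props <- as.list(records[i, setdiff(names(records), c("x", "y"))])
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(records$x[i], records$y[i])),
           properties = props)
    })
    fc <- list(type = "FeatureCollection", features = feats)
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    write_point_shapefile(records, path)
  }
  invisible(path)
}

# minimal ESRI point shapefile writer (.shp/.shx + .dbf via foreign)
write_point_shapefile <- function(records, path) {
  base <- sub("\\.shp$", "", path)
  n <- nrow(records)
  x <- records$x; y <- records$y
  bbox <- if (n > 0) c(min(x), min(y), max(x), max(y)) else rep(0, 4)
  rec_words <- 10L                      # 20 bytes: shape type + x + y
  file_words <- 50L + n * (4L + rec_words)
  shp <- file(paste0(base, ".shp"), "wb")
  shx <- file(paste0(base, ".shx"), "wb")
  hdr <- function(con, words) {
    writeBin(as.integer(c(9994, 0, 0, 0, 0, 0)), con, size = 4,
             endian = "big")
    writeBin(as.integer(words), con, size = 4, endian = "big")
    writeBin(as.integer(c(1000, 1)), con, size = 4, endian = "little")
    writeBin(as.double(c(bbox, 0, 0, 0, 0)), con, size = 8,
             endian = "little")
  }
  hdr(shp, file_words)
  hdr(shx, 50L + n * 4L)
  offset <- 50L
  for (i in seq_len(n)) {
    writeBin(as.integer(offset), shx, size = 4, endian = "big")
    writeBin(rec_words, shx, size = 4, endian = "big")
    writeBin(as.integer(c(i, rec_words)), shp, size = 4, endian = "big")
    writeBin(1L, shp, size = 4, endian = "little")
    writeBin(as.double(c(x[i], y[i])), shp, size = 8, endian = "little")
    offset <- offset + 4L + rec_words
  }
  close(shp); close(shx)
  attrs <- as.data.frame(records[, setdiff(names(records), c("x", "y")),
                                 drop = FALSE])
  if (ncol(attrs) == 0) attrs <- data.frame(id = seq_len(n))
  foreign::write.dbf(attrs, paste0(base, ".dbf"))
  invisible(paste0(base, ".shp"))
}

#' Read a point shapefile written by [write_individuals()]
#'
#' @param path the .shp path.
#' @return tibble with `x`, `y` and the .dbf attributes.
#' @export
read_point_shapefile <- function(path) {
  base <- sub("\\.shp$", "", path)
  con <- file(paste0(base, ".shp"), "rb")
  on.exit(close(con))
  seek(con, 24)
  words <- readBin(con, "integer", 1, size = 4, endian = "big")
  seek(con, 100)
  xs <- numeric(0); ys <- numeric(0)
  while (seek(con, NA) < 2 * words) {
    readBin(con, "integer", 2, size = 4, endian = "big")
    st <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(st) == 0) break
    xy <- readBin(con, "double", 2, size = 8, endian = "little")
    xs <- c(xs, xy[1]); ys <- c(ys, xy[2])
  }
  attrs <- foreign::read.dbf(paste0(base, ".dbf"), as.is = TRUE)
  dplyr::bind_cols(tibble::tibble(x = xs, y = ys), tibble::as_tibble(attrs))
}

#' Reconstruct an individual's chromatid from founder genomes
#'
#' Replays the recorded gamete table: starting from the recorded start
#' chromatid and flipping at each stored switch position, the contributing
#' parental chromatid is known at every locus; recursing to founders yields
#' the exact transmitted haplotype.
#'
#' @param id individual id.
#' @param chromatid 1 or 2.
#' @param tables [pedigree_tables()] output.
#' @param founder_genomes named list: founder id -> list(ch1=, ch2=) vectors.
#' @param L genome length.
#' @return length-L haplotype.
#' @export
replay_chromatid <- function(id, chromatid, tables, founder_genomes, L) {
  key <- as.character(id)
  if (key %in% names(founder_genomes)) {
    g <- founder_genomes[[key]]
    return(if (chromatid == 1) g$ch1 else g$ch2)
  }
  gam <- tables$gametes[tables$gametes$child == id &
                          tables$gametes$chromatid == chromatid, ]
  if (nrow(gam) != 1) stop("no gamete record for individual ", id)
  path <- integer(L)
  path[1] <- gam$start[[1]]
  flips <- gam$switches[[1]]
  if (L > 1) {
    sw <- integer(L - 1)
    sw[flips] <- 1L
    path <- (path[1] + c(0L, cumsum(sw))) %% 2L
  }
  parent <- gam$parent[[1]]
  p1 <- replay_chromatid(parent, 1, tables, founder_genomes, L)
  p2 <- replay_chromatid(parent, 2, tables, founder_genomes, L)
  ifelse(path == 0L, p1, p2)
}
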