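# Genomic feature tables (genes, QTLs), region overlap, and Fisher-exact
# category enrichment.

#' Read a feature/QTL interval table
#'
#' Two conventions are supported and normalized to internal 1-based
#' inclusive coordinates:
#' \itemize{
#'   \item `"bed"`: headerless, 0-based half-open columns
#'     chrom, start, end, name, (category) — start is incremented on read;
#'   \item `"tsv"`: header line, 1-based inclusive columns
#'     chrom, start_bp, end_bp, name, (category) — kept as-is.
#' }
#' Chromosome names are normalized by stripping a leading "chr"/"Chr"
#' prefix. Malformed lines (non-numeric coordinates, start > end after
#' normalization) raise errors naming the line number.
#'
#' @param path input file
#' @param format "bed" or "tsv"
#' @return object of class `feature_set`: data.frame chrom, start_bp,
#'   end_bp, name, category; attribute `source_format`
#' @export
read_features <- function(path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  header <- format == "tsv"
  raw <- utils::read.table(path, header = header, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "#")
  if (ncol(raw) < 4L) stop("feature table needs >= 4 columns")
  chrom <- normalize_chrom(raw[[1L]])
  start <- suppressWarnings(as.integer(raw[[2L]]))
  end <- suppressWarnings(as.integer(raw[[3L]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("non-numeric coordinates on line(s): ",
         paste(bad + as.integer(header), collapse = ", "))
  if (format == "bed") start <- start + 1L  # 0-based half-open -> 1-based
  bad <- which(start > end)
  if (length(bad))
    stop("start > end after normalization on line(s): ",
         paste(bad + as.integer(header), collapse = ", "))
  name <- raw[[4L]]
  if (anyDuplicated(name))
    stop("feature names must be unique within a source")
  category <- if (ncol(raw) >= 5L) raw[[5L]] else rep(NA_character_,
                                                      nrow(raw))
  out <- data.frame(chrom = chrom, start_bp = start, end_bp = end,
                    name = name, category = category,
                    stringsAsFactors = FALSE)
  structure(out, class = c("feature_set", "data.frame"),
            source_format = format)
}

#' Write a feature set back to BED (0-based half-open)
#'
#' @param features a `feature_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_features_bed <- function(features, path) {
  out <- data.frame(features$chrom, features$start_bp - 1L,
                    features$end_bp, features$name)
  if (!all(is.na(features$category))) out$category <- features$category
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

normalize_chrom <- function(x) sub("^[Cc]hr", "", x)

#' Overlap called regions with genomic features
#'
#' A feature hits a region iff the closed 1-based intervals share at least
#' `min_overlap_bp` base pairs (default 1: any overlap, so touching
#' endpoints count). A sorted sweep over per-chromosome interval lists
#' keeps the cost near linear.
#'
#' @param regions data.frame with chrom, start_bp, end_bp (e.g. from
#'   [call_fst_regions()])
#' @param features a `feature_set` (or compatible data.frame)
#' @param min_overlap_bp minimum shared base pairs to report a hit
#' @return data.frame region_chrom, region_start, region_end, name,
#'   category, overlap_bp
#' @export
overlap_features <- function(regions, features, min_overlap_bp = 1) {
  rc <- normalize_chrom(as.character(regions$chrom))
  fc <- normalize_chrom(as.character(features$chrom))
  rows <- list()
  for (ch in unique(rc)) {
    ri <- which(rc == ch)
    fi <- which(fc == ch)
    if (!length(fi)) next
    fi <- fi[order(features$start_bp[fi])]
    fstart <- features$start_bp[fi]
    fend <- features$end_bp[fi]
    for (r in ri) {
      rs <- regions$start_bp[r]; re <- regions$end_bp[r]
      # sweep: features sorted by start; candidates have start <= re
      cand <- fi[fstart <= re]
      if (!length(cand)) next
      ov <- pmin(features$end_bp[cand], re) -
        pmax(features$start_bp[cand], rs) + 1L
      hit <- ov >= min_overlap_bp
      if (!any(hit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        region_chrom = regions$chrom[r], region_start = rs,
        region_end = re, name = features$name[cand[hit]],
        category = features$category[cand[hit]],
        overlap_bp = ov[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(region_chrom = character(0),
                      region_start = integer(0), region_end = integer(0),
                      name = character(0), category = character(0),
                      overlap_bp = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Fisher-exact category enrichment of a gene list
#'
#' For each category in `category_map`, forms the 2x2 table of
#' (hit genes in category, hit genes not in category, background-only
#' genes in category, remainder) and computes the one-sided
#' over-representation p-value from the hypergeometric tail. `expected` is
#' the hit-list size times the category's background frequency and
#' `fold_enrichment = observed / expected`.
#'
#' @param hit_names character vector, must be a subset of
#'   `background_names`
#' @param background_names the gene universe (explicit by design: results
#'   depend strongly on it)
#' @param category_map data.frame (name, category) or named character
#'   vector name -> category; genes may appear in several categories via
#'   repeated rows
#' @param two_sided use the two-sided Fisher test instead
#' @return data.frame category, observed, expected, fold_enrichment,
#'   raw_p, sorted by raw_p
#' @export
fisher_enrichment <- function(hit_names, background_names, category_map,
                              two_sided = FALSE) {
  if (!length(background_names)) stop("empty background gene universe")
  if (!all(hit_names %in% background_names))
    stop("hit genes missing from the background: ",
         paste(utils::head(setdiff(hit_names, background_names), 5),
               collapse = ", "))
  if (!is.data.frame(category_map))
    category_map <- data.frame(name = names(category_map),
                               category = unname(category_map),
                               stringsAsFactors = FALSE)
  names(category_map)[1:2] <- c("name", "category")
  category_map <- category_map[category_map$name %in% background_names, ,
                               drop = FALSE]
  N <- length(unique(background_names))
  n <- length(unique(hit_names))
  cats <- unique(category_map$category)
  rows <- lapply(cats, function(cat) {
    members <- unique(category_map$name[category_map$category == cat])
    K <- length(members)
    obs <- length(intersect(hit_names, members))
    expected <- n * K / N
    p <- if (two_sided) {
      m <- matrix(c(obs, n - obs, K - obs, N - n - K + obs), 2L)
      stats::fisher.test(m)$p.value
    } else {
      stats::phyper(obs - 1, K, N - K, n, lower.tail = FALSE)
    }
    data.frame(category = cat, observed = obs, expected = expected,
               fold_enrichment = if (expected > 0) obs / expected else
                 NA_real_,
               raw_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$raw_p), , drop = FALSE]
}
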