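#' Construct a genetic map
#'
#' A monotone bp -> cM mapping for one chromosome, stored as anchor
#' points.  Positions must be strictly increasing and map positions
#' non-decreasing.
#'
#' @param pos_bp 1-based physical positions (strictly increasing).
#' @param pos_cM cumulative map positions in centimorgans
#'   (non-decreasing).
#' @param chrom chromosome label.
#' @return A data frame of class `genetic_map` with columns `pos_bp`,
#'   `pos_cM` and attribute `chrom`.
#' @export
genetic_map <- function(pos_bp, pos_cM, chrom = "1") {
  if (length(pos_bp) != length(pos_cM))
    stop("pos_bp and pos_cM lengths differ")
  if (length(pos_bp) < 1) stop("empty genetic map")
  if (any(diff(pos_bp) <= 0))
    stop("map positions must be strictly increasing in bp")
  if (any(diff(pos_cM) < 0))
    stop("map cM values must be non-decreasing")
  structure(data.frame(pos_bp = as.numeric(pos_bp),
                       pos_cM = as.numeric(pos_cM)),
            chrom = chrom, class = c("genetic_map", "data.frame"))
}

#' Read a genetic map file
#'
#' Accepts two dialects, auto-detected: a headered HapMap-style rate file
#' (columns including `position` and a `rate` in cM/Mb; cumulative cM is
#' obtained by trapezoid-free left integration of the rate column), or a
#' headerless PLINK `.map` file with columns chrom, id, cM, bp.
#'
#' @param path map file path.
#' @param chrom chromosome to keep when the file covers several;
#'   default takes the first chromosome present.
#' @return A `genetic_map`.
#' @export
read_genetic_map <- function(path, chrom = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]{3}", first)
  if (has_header && grepl("rate", tolower(first))) {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    pos_col <- grep("pos", names(tab))[1]
    rate_col <- grep("rate", names(tab))[1]
    chr_col <- grep("chr", names(tab))[1]
    if (is.na(pos_col) || is.na(rate_col)) stop("unknown map dialect: ", path)
    chr <- if (!is.na(chr_col)) as.character(tab[[chr_col]]) else "1"
    keep_chr <- if (is.null(chrom)) chr[1] else chrom
    tab <- tab[chr == keep_chr, , drop = FALSE]
    bp <- as.numeric(tab[[pos_col]])
    rate <- as.numeric(tab[[rate_col]])
    o <- order(bp)
    bp <- bp[o]; rate <- rate[o]
    # rate[i] applies over the interval [bp[i], bp[i+1])
    cm <- c(0, cumsum(rate[-length(rate)] * diff(bp) / 1e6))
    return(genetic_map(bp, cm, chrom = keep_chr))
  }
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 4) stop("unknown map dialect: ", path)
  names(tab) <- c("chrom", "id", "cm", "bp")
  keep_chr <- if (is.null(chrom)) as.character(tab$chrom[1]) else chrom
  tab <- tab[as.character(tab$chrom) == keep_chr, , drop = FALSE]
  o <- order(tab$bp)
  genetic_map(tab$bp[o], tab$cm[o], chrom = keep_chr)
}

#' Interpolate map position (cM) at physical positions
#'
#' Piecewise-linear interpolation between map anchors; positions outside
#' the anchor span are linearly extrapolated with the terminal segment's
#' rate and flagged via the `extrapolated` attribute.
#'
#' @param map a `genetic_map`.
#' @param pos_bp physical positions to interpolate.
#' @return Numeric cM positions, with logical attribute `extrapolated`.
#' @export
interpolate_cm <- function(map, pos_bp) {
  if (nrow(map) == 0) stop("empty genetic map")
  x <- map$pos_bp
  y <- map$pos_cM
  if (nrow(map) == 1) {
    out <- rep(y, length(pos_bp))
  } else {
    out <- stats::approx(x, y, xout = pos_bp, rule = 2)$y
    lo <- pos_bp < x[1]
    hi <- pos_bp > x[length(x)]
    k <- length(x)
    if (any(lo)) {
      slope <- (y[2] - y[1]) / (x[2] - x[1])
      out[lo] <- y[1] + slope * (pos_bp[lo] - x[1])
    }
    if (any(hi)) {
      slope <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
      out[hi] <- y[k] + slope * (pos_bp[hi] - x[k])
    }
  }
  attr(out, "extrapolated") <- pos_bp < x[1] | pos_bp > x[length(x)]
  out
}
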