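# internal helpers shared across modules

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Label connected components (8-connectivity)
#'
#' Cells are identified as 8-connected components of a binary mask, so that
#' diagonally touching pixels belong to the same cell.
#'
#' @param mask binary matrix (non-zero = foreground).
#' @return integer matrix of component labels (0 = background), labelled in
#'   column-major discovery order.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  label8_cpp(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)))
}

# pixel overlap counts between two labelled matrices; returns a matrix with
# rownames = labels of `a`, colnames = labels of `b`
overlap_counts <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sel <- a > 0 & b > 0
  la <- sort(unique(a[a > 0]))
  lb <- sort(unique(b[b > 0]))
  out <- matrix(0L, length(la), length(lb), dimnames = list(la, lb))
  if (any(sel)) {
    tab <- table(factor(a[sel], levels = la), factor(b[sel], levels = lb))
    out[] <- as.integer(tab)
  }
  out
}

# inverse-warp sampler: result(i, j) = img(sy[i,j], sx[i,j]) with coordinates
# clamped to the image (edge replication).  `method` "bilinear" for intensity
# channels, "nearest" for masks and weight maps.
warp_channel <- function(img, sy, sx, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(img); W <- ncol(img)
  sy <- pmin(pmax(sy, 1), H)
  sx <- pmin(pmax(sx, 1), W)
  if (method == "nearest") {
    out <- img[cbind(as.vector(round(sy)), as.vector(round(sx)))]
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
    fy <- sy - y0; fx <- sx - x0
    out <- (1 - fy) * (1 - fx) * img[cbind(as.vector(y0), as.vector(x0))] +
           (1 - fy) * fx       * img[cbind(as.vector(y0), as.vector(x1))] +
           fy       * (1 - fx) * img[cbind(as.vector(y1), as.vector(x0))] +
           fy       * fx       * img[cbind(as.vector(y1), as.vector(x1))]
  }
  matrix(out, H, W)
}

# round-half-up at `digits` decimals (reporting convention for error rates)
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

# run-length encoding of a pixel index set (column-major linear indices),
# used in the lineage JSON serialization
rle_region <- function(idx) {
  idx <- sort(as.integer(idx))
  if (length(idx) == 0L) return(list(start = integer(0), length = integer(0)))
  breaks <- c(0L, which(diff(idx) != 1L), length(idx))
  list(start = idx[breaks[-length(breaks)] + 1L],
       length = diff(breaks))
}

rle_decode <- function(rle) {
  if (length(rle$start) == 0L) return(integer(0))
  unlist(mapply(function(s, l) seq.int(s, length.out = l),
                rle$start, rle$length, SIMPLIFY = FALSE))
}
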