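# Plain-text PNM (ASCII PGM/PPM) image input/output. The environment this
# package targets has no PNG/TIFF reader available to R, and PNM is the
# standard uncompressed interchange format every image toolchain
# (ImageMagick, netpbm, scikit-image, OpenCV) can read and write.

#' Read a plain PNM image (ASCII P1/P2/P3)
#'
#' @param path file path.
#' @return numeric matrix (P1/P2) or height x width x 3 array (P3), scaled
#'   to [0,1] by the header's maximum value.
#' @export
read_pnm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  magic <- tok[1]
  if (!magic %in% c("P1", "P2", "P3"))
    stop("unsupported PNM magic '", magic, "': only plain P1/P2/P3",
         call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  if (magic == "P1") {
    vals <- as.numeric(tok[-(1:3)])
    return(matrix(1 - vals, nrow = h, ncol = w, byrow = TRUE))
  }
  maxv <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)]) / maxv
  if (magic == "P2") return(matrix(vals, nrow = h, ncol = w, byrow = TRUE))
  px <- matrix(vals, ncol = 3L, byrow = TRUE)
  out <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) out[, , ch] <- matrix(px[, ch], nrow = h, byrow = TRUE)
  out
}

#' Write a gray image or binary mask as plain PGM (ASCII P2)
#'
#' Values are clipped to [0,1] and quantized to 8 bits; logical masks come
#' out as 0/255.
#'
#' @param img numeric matrix in [0,1] or logical matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  m <- round(pmin(pmax(img * 1, 0), 1) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  write(t(m), file = con, ncolumns = min(ncol(m), 16L))
  invisible(path)
}
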