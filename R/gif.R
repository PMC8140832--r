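# Minimal animated GIF89a writer.
#
# Frames are H x W x 3 arrays in [0, 1] (as returned by png::readPNG).
# Colors are quantised to a shared global palette (bit-depth reduction
# when more than 256 distinct colors occur). Pixel data are LZW-encoded
# with the standard variable-width code stream, dictionary reset at 4096
# codes.

# Pack an integer code stream into GIF's LSB-first byte stream.
pack_codes <- function(codes, widths) {
  nbits <- sum(widths)
  bytes <- raw(ceiling(nbits / 8))
  bitpos <- 0L
  for (i in seq_along(codes)) {
    v <- codes[i]
    for (b in seq_len(widths[i])) {
      if (bitwAnd(v, 1L) == 1L) {
        byte_i <- bitpos %/% 8L + 1L
        bytes[byte_i] <- as.raw(bitwOr(as.integer(bytes[byte_i]),
                                       bitwShiftL(1L, bitpos %% 8L)))
      }
      v <- bitwShiftR(v, 1L)
      bitpos <- bitpos + 1L
    }
  }
  bytes
}

# LZW-encode a vector of palette indices (0-based) for a given minimum
# code size; returns the packed raw bytes of the code stream.
lzw_encode <- function(idx, min_code_size) {
  clear <- bitwShiftL(1L, min_code_size)
  eoi <- clear + 1L
  codes <- integer(0)
  widths <- integer(0)
  reserve <- length(idx) + 16L
  codes <- integer(reserve); widths <- integer(reserve); nc <- 0L
  emit <- function(code, width) {
    nc <<- nc + 1L
    if (nc > length(codes)) { codes <<- c(codes, integer(reserve)); widths <<- c(widths, integer(reserve)) }
    codes[nc] <<- code; widths[nc] <<- width
  }
  dict <- new.env(hash = TRUE, size = 8192L)
  reset_dict <- function() {
    rm(list = ls(dict, all.names = TRUE), envir = dict)
  }
  next_code <- eoi + 1L
  code_size <- min_code_size + 1L
  emit(clear, code_size)
  prefix <- -1L
  for (k in idx) {
    if (prefix < 0L) { prefix <- k; next }
    key <- paste0(prefix, "_", k)
    hit <- dict[[key]]
    if (!is.null(hit)) {
      prefix <- hit
    } else {
      emit(prefix, code_size)
      dict[[key]] <- next_code
      next_code <- next_code + 1L
      if (next_code > bitwShiftL(1L, code_size) && code_size < 12L)
        code_size <- code_size + 1L
      if (next_code >= 4096L) {
        emit(clear, code_size)
        reset_dict()
        next_code <- eoi + 1L
        code_size <- min_code_size + 1L
      }
      prefix <- k
    }
  }
  if (prefix >= 0L) emit(prefix, code_size)
  emit(eoi, code_size)
  pack_codes(codes[seq_len(nc)], widths[seq_len(nc)])
}

u16 <- function(x) as.raw(c(bitwAnd(x, 255L), bitwShiftR(x, 8L)))

# Chunk a raw vector into <=255-byte GIF sub-blocks, with terminator.
sub_blocks <- function(bytes) {
  n <- length(bytes)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- min(i + 254L, n)
    out[[length(out) + 1L]] <- c(as.raw(j - i + 1L), bytes[i:j])
    i <- j + 1L
  }
  out[[length(out) + 1L]] <- as.raw(0L)
  do.call(c, out)
}

# Quantise frames to a shared palette of at most 256 colors by bit-depth
# reduction; returns list(palette = n x 3 integer 0..255, frames = list
# of 0-based index matrices).
quantize_frames <- function(frames) {
  to_key <- function(arr, levels) {
    rgb <- round(arr * (levels - 1)) / (levels - 1)
    r <- round(rgb[, , 1] * 255); g <- round(rgb[, , 2] * 255); b <- round(rgb[, , 3] * 255)
    r * 65536 + g * 256 + b
  }
  for (levels in c(256, 64, 32, 16, 8, 6, 4, 2)) {
    keys <- lapply(frames, to_key, levels = levels)
    uk <- sort(unique(unlist(lapply(keys, as.vector))))
    if (length(uk) <= 256) {
      pal <- cbind(uk %/% 65536, (uk %/% 256) %% 256, uk %% 256)
      idx <- lapply(keys, function(k) {
        m <- match(as.vector(t(k)), uk) - 1L  # row-major scan order
        matrix(m, nrow = nrow(k), byrow = TRUE)
      })
      return(list(palette = pal, frames = idx))
    }
  }
  stop("could not quantise frames to 256 colors")
}

#' Write an animated GIF
#'
#' Self-contained GIF89a encoder: frames share a global palette
#' (bit-depth-reduced when needed), pixel data are LZW-compressed, and a
#' Netscape looping block makes the animation repeat.
#'
#' @param frames list of H x W x 3 numeric arrays in \[0, 1\].
#' @param path output file.
#' @param delay_cs delay between frames in hundredths of a second.
#' @return the path, invisibly.
#' @export
write_gif <- function(frames, path, delay_cs = 10) {
  stopifnot(length(frames) >= 1)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3 && dim(f)[3] >= 3) f[, , 1:3, drop = FALSE]
    else stop("frames must be H x W x 3 arrays")
  })
  h <- dim(frames[[1]])[1]; w <- dim(frames[[1]])[2]
  q <- quantize_frames(frames)
  ncol_pal <- nrow(q$palette)
  bits <- max(2L, ceiling(log2(ncol_pal)))
  pal_size <- bitwShiftL(1L, bits)
  pal <- rbind(q$palette, matrix(0L, pal_size - ncol_pal, 3))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GIF89a"), con)
  ## logical screen descriptor with global color table
  writeBin(c(u16(w), u16(h),
             as.raw(bitwOr(0xF0L, bits - 1L)), as.raw(0L), as.raw(0L)), con)
  writeBin(as.raw(t(pal)), con)
  ## Netscape looping extension (loop forever)
  writeBin(c(as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
             as.raw(c(0x03, 0x01)), u16(0L), as.raw(0L)), con)
  for (fr in q$frames) {
    ## graphic control extension: delay, no disposal
    writeBin(c(as.raw(c(0x21, 0xF9, 0x04, 0x00)), u16(as.integer(delay_cs)),
               as.raw(c(0x00, 0x00))), con)
    ## image descriptor, no local color table
    writeBin(c(as.raw(0x2C), u16(0L), u16(0L), u16(w), u16(h), as.raw(0L)), con)
    mcs <- max(2L, bits)
    writeBin(as.raw(mcs), con)
    writeBin(sub_blocks(lzw_encode(as.vector(t(fr)), mcs)), con)
  }
  writeBin(as.raw(0x3B), con)
  invisible(path)
}
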