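# Plain-text and archive I/O: TVB-style connectome bundles, TSV sidecars,
# and BrainVision recordings.

# ---- minimal store-only ZIP writer -----------------------------------------
# The connectome bundle is a ZIP of whitespace-delimited text tables.
# Archives are written uncompressed (method 0) with hand-built headers;
# reading goes through utils::unzip (internal method).

# logical (unsigned) right shift on a 32-bit pattern stored as signed int
lshr32 <- function(x, n) {
  if (x >= 0) bitwShiftR(x, n)
  else bitwOr(bitwShiftR(bitwAnd(x, 2147483647L), n),
              bitwShiftL(1L, 31L - n))
}

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    crc <- i
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 1L) != 0L)
        bitwXor(lshr32(crc, 1L), -306674912L)  # 0xEDB88320 as signed
      else lshr32(crc, 1L)
    }
    tab[i + 1] <- crc
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(lshr32(crc, 8L), crc32_table[idx + 1])
  }
  bitwXor(crc, -1L)
}

write_zip_store <- function(files, zipfile) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entries <- list()
  offset <- 0
  for (name in names(files)) {
    data <- files[[name]]
    if (is.character(data)) data <- charToRaw(paste0(data, collapse = ""))
    crc <- crc32(data)
    nb <- length(data)
    nname <- charToRaw(name)
    w4(0x04034b50); w2(20); w2(0); w2(0); w2(0); w2(0)
    w4(crc); w4(nb); w4(nb); w2(length(nname)); w2(0)
    writeBin(nname, con); writeBin(data, con)
    entries[[name]] <- list(crc = crc, size = nb, offset = offset)
    offset <- offset + 30 + length(nname) + nb
  }
  cd_offset <- offset
  for (name in names(entries)) {
    e <- entries[[name]]
    nname <- charToRaw(name)
    w4(0x02014b50); w2(20); w2(20); w2(0); w2(0); w2(0); w2(0)
    w4(e$crc); w4(e$size); w4(e$size); w2(length(nname))
    w2(0); w2(0); w2(0); w2(0); w4(0); w4(e$offset)
    writeBin(nname, con)
    offset <- offset + 46 + length(nname)
  }
  w4(0x06054b50); w2(0); w2(0); w2(length(entries)); w2(length(entries))
  w4(offset - cd_offset); w4(cd_offset); w2(0)
  invisible(zipfile)
}

fmt_table <- function(m, digits = 10) {
  paste0(apply(m, 1, function(r) paste(formatC(r, digits = digits,
                                               format = "g"),
                                       collapse = " ")),
         "\n")
}

# ---- connectome bundle ------------------------------------------------------

#' Write a structural bundle as a TVB-style connectome ZIP
#'
#' The archive holds whitespace-delimited text tables: `weights.txt`
#' (R x R), `tract_lengths.txt` (R x R), `centres.txt` (label x y z) and
#' `cortical.txt` (one 0/1 flag per region).
#'
#' @param connectome A `vep_connectome`.
#' @param parcellation A `vep_parcellation`.
#' @param path Output `.zip` path.
#' @return The path, invisibly.
#' @export
write_connectome_bundle <- function(connectome, parcellation, path) {
  centres <- paste0(parcellation$region_labels, " ",
                    apply(parcellation$centers, 1,
                          function(r) paste(formatC(r, digits = 10,
                                                    format = "g"),
                                            collapse = " ")),
                    "\n")
  files <- list(
    "weights.txt" = fmt_table(connectome$weights),
    "tract_lengths.txt" = fmt_table(connectome$tract_lengths),
    "centres.txt" = centres,
    "cortical.txt" = paste0(as.integer(parcellation$cortical), "\n"))
  write_zip_store(files, path)
  invisible(path)
}

#' Read a TVB-style connectome ZIP
#'
#' @param path Path to the archive.
#' @return List with `connectome` (`vep_connectome`) and `parcellation`
#'   (`vep_parcellation`, centers and labels only).
#' @export
read_connectome_bundle <- function(path) {
  tmp <- tempfile("bundle")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  got <- utils::unzip(path, exdir = tmp)
  need <- function(f) {
    p <- file.path(tmp, f)
    if (!file.exists(p))
      stop("connectome bundle is missing '", f, "' (", path, ")")
    p
  }
  W <- as.matrix(read.table(need("weights.txt")))
  dimnames(W) <- NULL
  if (nrow(W) != ncol(W)) stop("weights.txt is not square in ", path)
  L <- if (file.exists(file.path(tmp, "tract_lengths.txt"))) {
    m <- as.matrix(read.table(file.path(tmp, "tract_lengths.txt")))
    dimnames(m) <- NULL
    m
  } else matrix(0, nrow(W), ncol(W))
  cen <- read.table(need("centres.txt"), stringsAsFactors = FALSE)
  if (ncol(cen) != 4) stop("centres.txt must have label x y z columns")
  cortical <- if (file.exists(file.path(tmp, "cortical.txt")))
    as.logical(scan(file.path(tmp, "cortical.txt"), quiet = TRUE))
  else rep(TRUE, nrow(W))
  con <- structure(list(weights = W, tract_lengths = L),
                   class = "vep_connectome")
  parc <- structure(list(region_labels = cen[[1]],
                         centers = unname(as.matrix(cen[, 2:4])),
                         cortical = cortical, R = nrow(W)),
                    class = "vep_parcellation")
  list(connectome = con, parcellation = parc)
}

# ---- TSV sidecars -----------------------------------------------------------

#' Write / read a gain matrix as TSV
#'
#' `R` rows by `N` columns of tab-separated floats, no header.
#'
#' @param gain R x N matrix.
#' @param path File path.
#' @return `write_gain_tsv`: the path, invisibly. `read_gain_tsv`: the
#'   matrix.
#' @export
write_gain_tsv <- function(gain, path) {
  write.table(gain, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gain_tsv
#' @export
read_gain_tsv <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  m
}

#' Write / read electrode coordinates as BIDS-style TSV
#'
#' Columns `name`, `x`, `y`, `z` (mm), tab-separated with a header.
#'
#' @param electrodes A `vep_electrodes` object (or data frame with the
#'   columns above).
#' @param path File path.
#' @return The path (write) or a data frame (read).
#' @export
write_electrodes_tsv <- function(electrodes, path) {
  df <- if (inherits(electrodes, "vep_electrodes"))
    data.frame(name = electrodes$contacts$label,
               x = electrodes$contacts$x,
               y = electrodes$contacts$y,
               z = electrodes$contacts$z)
  else electrodes
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_electrodes_tsv
#' @export
read_electrodes_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write an EZ hypothesis as TSV
#'
#' Columns `region`, `ev`, `zone`.
#'
#' @param hypothesis An [ez_hypothesis()].
#' @param region_labels Labels used when the hypothesis has none.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_hypothesis_tsv <- function(hypothesis, path, region_labels = NULL) {
  labs <- hypothesis$region_labels
  if (is.null(labs)) labs <- region_labels
  if (is.null(labs)) labs <- sprintf("Region-%03d", seq_along(hypothesis$ev))
  df <- data.frame(region = labs, ev = hypothesis$ev,
                   zone = hypothesis$zones)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- BrainVision ------------------------------------------------------------

#' Write a BrainVision recording
#'
#' Produces the standard triplet: text header (`.vhdr`), marker file
#' (`.vmrk`) and raw multiplexed IEEE float32 little-endian samples
#' (`.eeg`). Units are declared microvolt-like; simulated amplitudes are
#' arbitrary units scaled for display.
#'
#' @param ts C x T numeric matrix, channel labels as row names.
#' @param fs Sampling rate in Hz.
#' @param basepath Output path without extension.
#' @param markers Optional data frame with columns `type`, `description`,
#'   `position` (sample, 1-based), `length` (samples).
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(ts, fs, basepath, markers = NULL) {
  stopifnot(is.matrix(ts), !is.null(rownames(ts)))
  base <- basename(basepath)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(ts)),
    paste0("SamplingInterval=", format(1e6 / fs, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(ts)), rownames(ts)))
  writeLines(hdr, paste0(basepath, ".vhdr"), useBytes = TRUE)
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0")
  if (!is.null(markers) && nrow(markers) > 0)
    mk <- c(mk, sprintf("Mk%d=%s,%s,%d,%d,0",
                        seq_len(nrow(markers)) + 1L,
                        markers$type, markers$description,
                        as.integer(markers$position),
                        as.integer(markers$length)))
  writeLines(mk, paste0(basepath, ".vmrk"), useBytes = TRUE)
  con <- file(paste0(basepath, ".eeg"), "wb")
  writeBin(as.vector(ts), con, size = 4, endian = "little")
  close(con)
  invisible(paste0(basepath, ".vhdr"))
}

#' Read a BrainVision recording
#'
#' Supports the subset written by [write_brainvision()]: multiplexed
#' IEEE float32 binary data with a text header and marker file.
#'
#' @param vhdr Path to the `.vhdr` header.
#' @return List with `ts` (C x T matrix, labelled rows), `fs`, and
#'   `markers` (data frame, possibly empty).
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, encoding = "UTF-8")
  getval <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(ln) == 0) stop("missing ", key, " in ", vhdr)
    sub(paste0("^", key, "="), "", ln[1])
  }
  if (getval("DataFormat") != "BINARY" ||
      getval("BinaryFormat") != "IEEE_FLOAT_32" ||
      getval("DataOrientation") != "MULTIPLEXED")
    stop("unsupported BrainVision variant in ", vhdr)
  nch <- as.integer(getval("NumberOfChannels"))
  fs <- 1e6 / as.numeric(getval("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- sub(",.*$", "", sub("^Ch[0-9]+=", "", ch_lines))
  eeg <- file.path(dirname(vhdr), getval("DataFile"))
  n <- file.info(eeg)$size / 4
  con <- file(eeg, "rb")
  x <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  close(con)
  ts <- matrix(x, nrow = nch)
  rownames(ts) <- labels
  vmrk <- file.path(dirname(vhdr), sub("\\.vhdr$", ".vmrk", basename(vhdr)))
  markers <- data.frame(type = character(), description = character(),
                        position = integer(), length = integer())
  if (file.exists(vmrk)) {
    ml <- grep("^Mk[0-9]+=", readLines(vmrk, encoding = "UTF-8"),
               value = TRUE)
    parts <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
    parts <- parts[vapply(parts, length, 1L) >= 4]
    if (length(parts) > 0)
      markers <- data.frame(
        type = vapply(parts, `[`, "", 1),
        description = vapply(parts, `[`, "", 2),
        position = as.integer(vapply(parts, `[`, "", 3)),
        length = as.integer(vapply(parts, `[`, "", 4)),
        stringsAsFactors = FALSE)
  }
  list(ts = ts, fs = fs, markers = markers)
}
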