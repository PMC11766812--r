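## Flow-cytometry stage: event tables, polygonal gating in the FSC-SSC
## plane, doublet-corrected mean fluorescence and stock-background
## subtraction.
##
## Doublet correction: with Ntot events and mean fluorescence I in a gate G1
## holding singlets plus doublets, and N2 doublet events in a sub-gate G2,
## the mean fluorescence per *bead* is Ntot * I / (Ntot + N2), because each
## doublet event carries the summed fluorescence of two beads.

#' Cytometry event table
#'
#' @param FSC,SSC,FL4 per-event forward scatter, side scatter (a.u.) and
#'   calibrated fluorescence (ERF); equal lengths, finite, `FL4 >= 0`.
#' @param sample_id optional sample label.
#' @return data frame of class `event_table`.
#' @export
event_table <- function(FSC, SSC, FL4, sample_id = NA_character_) {
  .check_finite(FSC, "FSC"); .check_finite(SSC, "SSC")
  .check_finite(FL4, "FL4")
  if (length(FSC) != length(SSC) || length(FSC) != length(FL4))
    .stopf("FSC, SSC, FL4 must have equal length")
  if (any(FL4 < 0)) .stopf("FL4 must be >= 0")
  structure(data.frame(FSC = FSC, SSC = SSC, FL4 = FL4),
            sample_id = sample_id,
            class = c("event_table", "data.frame"))
}

#' Polygonal gate in the FSC-SSC plane
#'
#' @param name gate label.
#' @param vertices matrix (or data frame) with columns FSC, SSC; at least 3
#'   rows; the polygon must be simple (non-self-intersecting).
#' @return object of class `gate`.
#' @export
gate <- function(name, vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) .stopf("gate '%s': polygon needs >= 3 vertices", name)
  .check_finite(v, "gate vertices")
  if (.polygon_self_intersects(v))
    .stopf("gate '%s': polygon is self-intersecting", name)
  structure(list(name = name, vertices = v[, 1:2, drop = FALSE]),
            class = "gate")
}

#' @export
print.gate <- function(x, ...) {
  cat(sprintf("<gate> '%s', %d vertices\n", x$name, nrow(x$vertices)))
  invisible(x)
}

## segment intersection test for polygon simplicity (small vertex counts)
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next                  # adjacent via wrap-around
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

## boundary-inclusive point-in-polygon, vectorized ray casting.
## Events exactly on an edge or vertex count as inside (deterministic on
## grid-valued synthetic data).
.points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    ## boundary test: collinear and within bounding box
    d <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    onseg <- abs(d) <= 1e-9 * (abs(xj - xi) + abs(yj - yi) + 1) &
      px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | onseg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Apply a polygonal gate to an event table
#'
#' Events strictly inside or on the boundary of the polygon are kept.
#'
#' @param events an [event_table()].
#' @param g a [gate()].
#' @return list with `events` (gated subset), `count`, and `mean_FL4`
#'   (`NaN`, with a warning-free `empty = TRUE` flag, when no event falls in
#'   the gate).
#' @export
apply_gate <- function(events, g) {
  keep <- .points_in_polygon(events$FSC, events$SSC, g$vertices)
  sub <- events[keep, , drop = FALSE]
  list(events = sub, count = nrow(sub),
       mean_FL4 = if (nrow(sub)) mean(sub$FL4) else NaN,
       empty = nrow(sub) == 0L)
}

#' Gating result (Ntot, I, N2)
#'
#' @param N_tot event count in the singlet+doublet gate G1.
#' @param I_FL4 arithmetic mean FL4 in G1, ERF.
#' @param N_2 doublet event count in gate G2 (a subset of G1).
#' @return object of class `gating_result`.
#' @export
gating_result <- function(N_tot, I_FL4, N_2) {
  if (N_tot < 0 || N_2 < 0) .stopf("counts must be >= 0")
  structure(list(N_tot = N_tot, I_FL4 = I_FL4, N_2 = N_2),
            class = "gating_result")
}

#' Gate an event table with the G1/G2 pair
#'
#' Reads Ntot and the mean FL4 in G1 (singlets plus doublets) and the
#' doublet count N2 in G2. G2 is treated as a subset of G1.
#'
#' @param events an [event_table()].
#' @param g1,g2 [gate()]s for all beads and for doublets.
#' @return a [gating_result()].
#' @export
gate_statistics <- function(events, g1, g2) {
  a1 <- apply_gate(events, g1)
  a2 <- apply_gate(a1$events, g2)
  gating_result(a1$count, a1$mean_FL4, a2$count)
}

#' Doublet-corrected mean fluorescence per bead
#'
#' `Ntot * I / (Ntot + N2)`: each doublet event carries two beads' summed
#' fluorescence, so the per-bead mean divides the gate total by the bead
#' count `Ntot + N2`.
#'
#' @param result a [gating_result()].
#' @return corrected mean, ERF.
#' @export
doublet_corrected_mean <- function(result) {
  if (result$N_tot + result$N_2 <= 0)
    .stopf("doublet correction undefined: no events (Ntot + N2 = 0)")
  result$N_tot * result$I_FL4 / (result$N_tot + result$N_2)
}

#' Stock-bead background reference
#'
#' Mean of the stock-bead replicate measurements taken at the start of an
#' experiment; the zero point of the calibration curve.
#'
#' @param replicates per-replicate mean fluorescences, ERF.
#' @return object of class `background_reference` with `I_stock` and
#'   `n_replicates`.
#' @export
background_reference <- function(replicates) {
  if (length(replicates) < 1L) .stopf("need >= 1 stock replicate")
  .check_finite(replicates, "replicates")
  structure(list(I_stock = mean(replicates),
                 n_replicates = length(replicates)),
            class = "background_reference")
}

#' Subtract the stock-bead background
#'
#' Negative results are reported as-is by default so the (0, 0) calibration
#' anchor stays unbiased; clipping at zero is opt-in.
#'
#' @param corrected doublet-corrected mean, ERF.
#' @param reference a [background_reference()].
#' @param clip clip negative results at 0.
#' @return background-subtracted fluorescence, ERF.
#' @export
background_subtract <- function(corrected, reference, clip = FALSE) {
  out <- corrected - reference$I_stock
  if (clip) out <- pmax(out, 0)
  out
}

#' Read cytometry events
#'
#' CSV is the primary interchange format (header columns mapped via
#' `columns`); FCS 3.0/3.1 list-mode files with float data are read through
#' a minimal keyword/channel parser.
#'
#' @param path file path.
#' @param format `"csv"` or `"fcs"`.
#' @param columns named character vector mapping `FSC`, `SSC`, `FL4` to the
#'   file's column or `$PnN` channel names.
#' @param sample_id optional sample label.
#' @return an [event_table()].
#' @export
read_events <- function(path, format = c("csv", "fcs"),
                        columns = c(FSC = "FSC", SSC = "SSC", FL4 = "FL4"),
                        sample_id = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "csv") {
    if (file.size(path) == 0L) .stopf("empty event file: %s", path)
    df <- utils::read.csv(path)
    if (nrow(df) == 0L) .stopf("event file has no rows: %s", path)
  } else {
    df <- .read_fcs(path)
  }
  miss <- columns[!(columns %in% names(df))]
  if (length(miss))
    .stopf("missing channel column(s): %s", paste(miss, collapse = ", "))
  event_table(df[[columns[["FSC"]]]], df[[columns[["SSC"]]]],
              df[[columns[["FL4"]]]], sample_id = sample_id)
}

#' Write cytometry events
#'
#' @param events an [event_table()].
#' @param path output path.
#' @param format `"csv"` (full precision) or `"fcs"` (FCS 3.0, float32).
#' @export
write_events <- function(events, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- as.data.frame(events)
    ## full precision so a write -> read round trip is bit-exact
    con <- file(path, "w")
    writeLines(paste(names(df), collapse = ","), con)
    cols <- lapply(df, function(x) base::format(x, digits = 17))
    writeLines(do.call(paste, c(cols, sep = ",")), con)
    close(con)
  } else {
    .write_fcs(as.data.frame(events), path)
  }
  invisible(path)
}

## --- minimal FCS 3.0 list-mode support (float32, little endian) ----------

.read_fcs <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  if (substr(header, 1, 3) != "FCS") .stopf("not an FCS file: %s", path)
  offs <- suppressWarnings(as.numeric(trimws(
    substring(header, c(11, 19, 27, 35), c(18, 26, 34, 42)))))
  if (anyNA(offs)) .stopf("malformed FCS header: %s", path)
  seek(con, offs[1])
  txt <- rawToChar(readBin(con, "raw", offs[2] - offs[1] + 1))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  keys <- parts[seq(1, length(parts) - 1, by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(vals, toupper(trimws(keys)))
  npar <- as.integer(kw[["$PAR"]]); ntot <- as.integer(kw[["$TOT"]])
  if (toupper(kw[["$MODE"]]) != "L") .stopf("only list-mode FCS supported")
  dtype <- toupper(kw[["$DATATYPE"]])
  if (!dtype %in% c("F", "D")) .stopf("only float FCS data supported")
  size <- if (dtype == "F") 4L else 8L
  endian <- if (kw[["$BYTEORD"]] %in% c("1,2,3,4")) "little" else "big"
  beg <- as.numeric(kw[["$BEGINDATA"]]); if (is.na(beg) || beg == 0) beg <- offs[3]
  seek(con, beg)
  vals <- readBin(con, "numeric", n = npar * ntot, size = size,
                  endian = endian)
  m <- matrix(vals, ncol = npar, byrow = TRUE)
  nm <- vapply(seq_len(npar), function(i) kw[[sprintf("$P%dN", i)]],
               character(1))
  df <- as.data.frame(m)
  names(df) <- nm
  df
}

.write_fcs <- function(df, path) {
  npar <- ncol(df); ntot <- nrow(df)
  kws <- c("$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
           "$PAR" = as.character(npar), "$TOT" = as.character(ntot),
           "$NEXTDATA" = "0")
  for (i in seq_len(npar)) {
    kws[sprintf("$P%dN", i)] <- names(df)[i]
    kws[sprintf("$P%dB", i)] <- "32"
    kws[sprintf("$P%dE", i)] <- "0,0"
    kws[sprintf("$P%dR", i)] <- format(ceiling(max(df[[i]], 1)) + 1,
                                       scientific = FALSE)
  }
  data_len <- 4L * npar * ntot
  ## iterate: text length depends on the data offsets it encodes
  text_start <- 58L
  make_text <- function(data_beg, data_end) {
    k <- c(kws, "$BEGINDATA" = as.character(data_beg),
           "$ENDDATA" = as.character(data_end))
    paste0("/", paste(names(k), unname(k), sep = "/", collapse = "/"), "/")
  }
  txt <- make_text(0, 0)
  for (it in 1:5) {
    data_beg <- text_start + nchar(txt)
    data_end <- data_beg + data_len - 1L
    new <- make_text(data_beg, data_end)
    if (nchar(new) == nchar(txt)) { txt <- new; break }
    txt <- new
  }
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_start + nchar(txt) - 1L,
                    data_beg, data_end, 0L, 0L)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.numeric(t(as.matrix(df))), con, size = 4L, endian = "little")
  invisible(path)
}
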