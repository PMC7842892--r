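# SPICE netlist export and round-trip reading. The netlist makes the
# realized network topology auditable and enables cross-validation against
# an external circuit simulator.

#' Export a network as a SPICE netlist
#'
#' One line per element (`Rxxx`/`Cxxx node_a node_b value`; element names
#' encode layer, orientation and segment, e.g. `Czin3`, `Rron7`), a
#' sinusoidal source line between the source node and ground, and `.end`.
#' Ground is written as node `0`. The source line carries the peak
#' amplitude `v_pp / 2` (SPICE `SIN` sources take peak values); the RMS
#' drive used by the in-package solver is `v_pp / (2 sqrt 2)`, as noted in
#' the header comment.
#'
#' @param network A `circuit_network`.
#' @param path Optional file path; if given the netlist is written there.
#' @return The netlist as a character vector of lines (invisibly when
#'   `path` is given).
#' @examples
#' nl <- export_netlist(build_network(well_parameters()))
#' length(grep("^[RC]", nl))  # 171 element lines
#' @export
export_netlist <- function(network, path = NULL) {
  stopifnot(inherits(network, "circuit_network"))
  el <- network$elements
  node <- function(x) ifelse(x == network$ground, "0", x)
  v_pp <- network$drive$v_pp
  freq <- network$drive$frequency
  lines <- c(
    "* equivalent-circuit network of a plasma-exposed culture well",
    sprintf("* source amplitude below is peak (v_pp/2 = %.15g V); RMS drive = v_pp/(2*sqrt(2)) = %.15g V",
            v_pp / 2, network$drive$v_rms),
    sprintf("%s %s %s %.15g", el$id, node(el$node_a), node(el$node_b),
            el$value),
    sprintf("V1 %s 0 SIN(0 %.15g %.15g)", node(network$source_node),
            v_pp / 2, freq),
    ".end"
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

.parse_element_id <- function(id) {
  # R0n<k>/R1n<k>: buffer; C(z|r)(i|o)n<k>: membrane; R(z|r)(i|o)n<k>:
  # cytoplasm; C0n<k>: plate. Anything else: unannotated.
  out <- tibble::tibble(id = id, layer = NA_character_,
                        orientation = NA_character_, side = NA_character_,
                        segment = NA_integer_)
  pat <- "^([RC])([0zr1])([io]?)n([0-9]+)$"
  ok <- grepl(pat, id)
  if (!any(ok)) return(out)
  kind_c <- sub(pat, "\\1", id[ok])
  axis_c <- sub(pat, "\\2", id[ok])
  side_c <- sub(pat, "\\3", id[ok])
  seg_c <- as.integer(sub(pat, "\\4", id[ok]))
  layer <- ifelse(axis_c %in% c("0", "1"),
                  ifelse(kind_c == "R", "buffer", "plate"),
                  ifelse(kind_c == "C", "membrane", "cytoplasm"))
  orientation <- ifelse(axis_c %in% c("0", "z"), "vertical", "radial")
  out$layer[ok] <- layer
  out$orientation[ok] <- orientation
  out$side[ok] <- ifelse(side_c == "", NA_character_,
                         ifelse(side_c == "i", "in", "out"))
  out$segment[ok] <- seg_c
  out
}

#' Read a SPICE netlist back into a network
#'
#' Parses the dialect written by [export_netlist()]: comment lines (`*`),
#' `R`/`C` element lines, one `V` source line with a `SIN` specification,
#' and `.end`. Layer, orientation and segment annotations are recovered
#' from the element names; geometry annotations are not stored in a netlist
#' and are left `NA`.
#'
#' @param path File path, or a character vector of netlist lines.
#' @return A `circuit_network`.
#' @export
read_netlist <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path)
           else as.character(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "*")]
  lines <- lines[lines != ".end"]

  is_src <- grepl("^V", lines)
  if (sum(is_src) != 1)
    stop("netlist must contain exactly one V source line", call. = FALSE)
  src_tok <- strsplit(lines[is_src], "[[:space:]]+")[[1]]
  sin <- regmatches(lines[is_src],
                    regexec("SIN\\(([^)]*)\\)", lines[is_src]))[[1]][2]
  if (is.na(sin)) stop("source line lacks a SIN(...) spec", call. = FALSE)
  sin_num <- as.numeric(strsplit(trimws(sin), "[[:space:]]+")[[1]])
  amp <- sin_num[2]; freq <- sin_num[3]
  v_pp <- 2 * amp
  drive <- list(v_pp = v_pp, frequency = freq, omega = 2 * pi * freq,
                v_rms = v_pp / (2 * sqrt(2)))
  unzero <- function(x) ifelse(x == "0", "G", x)
  source_node <- unzero(src_tok[2])

  el_lines <- lines[!is_src]
  bad <- !grepl("^[RC][^[:space:]]*([[:space:]]+[^[:space:]]+){3}$",
                el_lines)
  if (any(bad))
    stop("unparseable netlist line(s): ",
         paste(el_lines[bad], collapse = "; "), call. = FALSE)
  tok <- strsplit(el_lines, "[[:space:]]+")
  id <- vapply(tok, `[[`, character(1), 1)
  elements <- dplyr::mutate(
    .parse_element_id(id),
    kind = ifelse(startsWith(id, "R"), "resistor", "capacitor"),
    value = vapply(tok, function(t) as.numeric(t[4]), numeric(1)),
    node_a = unzero(vapply(tok, `[[`, character(1), 2)),
    node_b = unzero(vapply(tok, `[[`, character(1), 3))
  )
  circuit_network(elements, source_node = source_node, drive = drive)
}
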