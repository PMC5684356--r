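#' Parse IgG glycan structure names
#'
#' IgG Fc glycans are biantennary complex-type structures described by four
#' features: the number of galactoses (\code{G0}/\code{G1}/\code{G2}), the
#' presence of a core fucose (\code{F}, added by FUT8), the presence of a
#' bisecting GlcNAc (\code{N}, added by MGAT3), and the number of sialic
#' acids (\code{S1}/\code{S2}, added by ST6Gal1). Sialic acid attaches to
#' galactose, so a structure can never carry more sialic acids than
#' galactoses.
#'
#' @param name character vector of structure names such as \code{"G2FS1"}.
#'   The grammar is \code{G[0-2] [F] [N] [S1|S2]}, in that order.
#' @return A data.frame with one row per name and columns \code{name},
#'   \code{gal} (0-2), \code{fuc} (logical), \code{bis} (logical) and
#'   \code{sia} (0-2).
#' @examples
#' parseGlycanName(c("G0", "G2FS1"))
#' @export
parseGlycanName <- function(name) {
  stopifnot(is.character(name), length(name) >= 1L)
  pat <- "^G([0-2])(F?)(N?)(S([1-2]))?$"
  bad <- !grepl(pat, name)
  if (any(bad))
    stop("malformed glycan name(s): ", paste(name[bad], collapse = ", "),
         " (expected grammar G[0-2][F][N][S1|S2])")
  gal <- as.integer(sub(pat, "\\1", name))
  fuc <- sub(pat, "\\2", name) == "F"
  bis <- sub(pat, "\\3", name) == "N"
  siaStr <- sub(pat, "\\5", name)
  sia <- ifelse(siaStr == "", 0L, as.integer(siaStr))
  viol <- sia > gal
  if (any(viol))
    stop("invalid glycan structure(s): ", paste(name[viol], collapse = ", "),
         " (sialic acid count exceeds galactose count; sialylation requires",
         " galactosylation)")
  data.frame(name = name, gal = gal, fuc = fuc, bis = bis, sia = sia,
             stringsAsFactors = FALSE)
}

#' Format glycan structure features as a name
#'
#' Inverse of \code{\link{parseGlycanName}}.
#'
#' @param gal,sia integer counts (0-2).
#' @param fuc,bis logicals.
#' @return character vector of structure names.
#' @export
formatGlycanName <- function(gal, fuc, bis, sia) {
  stopifnot(all(gal >= 0 & gal <= 2), all(sia >= 0 & sia <= 2),
            all(sia <= gal))
  paste0("G", gal, ifelse(fuc, "F", ""), ifelse(bis, "N", ""),
         ifelse(sia > 0, paste0("S", sia), ""))
}

.enzymeForFeature <- c(fuc = "FUT8", gal = "B4GalT1", bis = "MGAT3",
                       sia = "ST6Gal1")

#' Identify the single-sugar addition linking two structures
#'
#' Every reaction in the glycosylation pathway adds exactly one sugar unit.
#' Given two structures this returns the enzyme that converts the first into
#' the second by a single addition, or \code{NA} if the structures do not
#' differ by exactly one unit (in the a -> b direction).
#'
#' @param a,b structure names (character scalars or vectors of equal length).
#' @return character vector: one of \code{"FUT8"}, \code{"B4GalT1"},
#'   \code{"MGAT3"}, \code{"ST6Gal1"}, or \code{NA_character_}.
#' @examples
#' singleAddition("G1F", "G2F")   # B4GalT1
#' singleAddition("G0", "G0FN")   # NA: two additions
#' @export
singleAddition <- function(a, b) {
  sa <- parseGlycanName(a)
  sb <- parseGlycanName(b)
  dg <- sb$gal - sa$gal
  df <- sb$fuc - sa$fuc
  dn <- sb$bis - sa$bis
  ds <- sb$sia - sa$sia
  total <- abs(dg) + abs(df) + abs(dn) + abs(ds)
  out <- rep(NA_character_, nrow(sa))
  one <- total == 1L
  out[one & dg == 1L] <- .enzymeForFeature[["gal"]]
  out[one & df == 1L] <- .enzymeForFeature[["fuc"]]
  out[one & dn == 1L] <- .enzymeForFeature[["bis"]]
  out[one & ds == 1L] <- .enzymeForFeature[["sia"]]
  out
}

#' Glycoform labels
#'
#' A glycoform is a glycan structure attached to a specific IgG subclass
#' (IgG1, IgG2 -- which includes the indistinguishable IgG3 glycopeptides --
#' or IgG4). Column labels of glycomics matrices follow the convention
#' \code{"<subclass>_<structure>"}, e.g. \code{"IgG1_G0F"}.
#'
#' @param subclass character vector of subclass names.
#' @param structure character vector of structure names.
#' @return \code{glycoformLabel}: character labels.
#' @export
glycoformLabel <- function(subclass, structure) {
  paste(subclass, structure, sep = "_")
}

#' @rdname glycoformLabel
#' @param label character vector of glycoform labels.
#' @return \code{parseGlycoform}: data.frame with columns \code{subclass}
#'   and \code{structure} (validated against the structure grammar).
#' @export
parseGlycoform <- function(label) {
  parts <- regmatches(label, regexpr("_", label), invert = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("glycoform label(s) not of the form <subclass>_<structure>: ",
         paste(label[bad], collapse = ", "))
  subclass <- vapply(parts, `[[`, "", 1L)
  structure <- vapply(parts, `[[`, "", 2L)
  parseGlycanName(structure)  # validates
  data.frame(label = label, subclass = subclass, structure = structure,
             stringsAsFactors = FALSE)
}
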