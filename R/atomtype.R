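# SYBYL/Tripos atom-type alphabet for the count fingerprints.
#
# The fingerprint columns are: 33 base Tripos mol2 heavy-atom types, 10
# extra elements seen in metabolic reaction corpora, and one reserved PAD
# pseudo-type used to fill layers that lie beyond a molecule's radius.

.base_tripos_types <- c(
  "C.3", "C.2", "C.1", "C.ar", "C.cat",
  "N.3", "N.2", "N.1", "N.ar", "N.am", "N.pl3", "N.4",
  "O.3", "O.2", "O.co2",
  "S.3", "S.2", "S.O", "S.O2",
  "P.3",
  "F", "Cl", "Br", "I",
  "Si", "Li", "Na", "Mg", "Al", "K", "Ca", "Fe", "Cu"
)

.extra_types <- c("As", "Pt", "Co", "Mn", "Zn", "Se", "Ge", "Sn", "Gd", "B")

.pad_type <- "PAD"

#' The fingerprint atom-type alphabet
#'
#' Returns the fixed, ordered atom-type alphabet used for fingerprint
#' columns: 33 base SYBYL/Tripos mol2 atom types, 10 extra elements that
#' occur in metabolic reactions (As, Pt, Co, Mn, Zn, Se, Ge, Sn, Gd, B) and
#' one reserved `PAD` pseudo-type marking layers beyond the molecule's
#' radius.  The order is fixed and versioned; fingerprint serializations
#' embed `version`.
#'
#' @return a list with elements `base` (33 types), `extra` (10), `pad`,
#'   `types` (all 44, in column order) and `version`.
#' @export
#' @examples
#' length(atom_type_alphabet()$base)  # 33
atom_type_alphabet <- function() {
  list(
    base = .base_tripos_types,
    extra = .extra_types,
    pad = .pad_type,
    types = c(.base_tripos_types, .extra_types, .pad_type),
    version = "tripos33+10+pad/1"
  )
}

# OpenBabel SYBYL spellings occasionally differ from the canonical Tripos
# list; normalize before lookup.
.sybyl_aliases <- c(
  "S.o" = "S.O", "S.o2" = "S.O2", "S.O2" = "S.O2",
  "N.amide" = "N.am",
  "O.spc" = "O.3", "O.t3p" = "O.3",
  "H.spc" = "H", "H.t3p" = "H"
)

#' Assign the fingerprint atom type of one atom
#'
#' Maps an atom of a parsed molecule onto the fingerprint alphabet: the
#' SYBYL type perceived by OpenBabel for the 33 base types (aromatic ring
#' atoms get `C.ar`/`N.ar`, sp3/sp2/sp carbons `C.3`/`C.2`/`C.1`,
#' carboxylate oxygens `O.co2`, ...), or the bare element symbol for the
#' extra metabolic elements.
#'
#' @param mol a `molgraph`.
#' @param atom_index 1-based heavy-atom index.
#' @return a single atom-type name from [atom_type_alphabet()].
#' @export
assign_atom_type <- function(mol, atom_index) {
  stopifnot(inherits(mol, "molgraph"))
  if (atom_index < 1 || atom_index > mol$n) {
    stop("atom_index out of range: ", atom_index)
  }
  atom_types(mol)[atom_index]
}

# Vectorized typing for a whole molecule (cached by callers where hot).
atom_types <- function(mol) {
  ab <- atom_type_alphabet()
  ty <- mol$sybyl
  ali <- .sybyl_aliases[ty]
  ty[!is.na(ali)] <- ali[!is.na(ali)]
  out <- character(mol$n)
  for (i in seq_len(mol$n)) {
    t <- ty[i]
    if (t %in% ab$base) {
      out[i] <- t
    } else if (mol$elem[i] %in% ab$extra) {
      out[i] <- mol$elem[i]
    } else if (mol$elem[i] %in% ab$base) {
      # halogens and bare metals arrive as plain element symbols
      out[i] <- mol$elem[i]
    } else {
      # fall back on element.hybridization-insensitive base lookup
      el <- mol$elem[i]
      cand <- ab$base[startsWith(ab$base, paste0(el, "."))]
      if (length(cand)) {
        out[i] <- cand[1]
      } else {
        stop(sprintf("unknown atom type '%s' (element %s) outside alphabet",
                     t, el))
      }
    }
  }
  out
}
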