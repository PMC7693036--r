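# Built-in reference schemes.
#
# Role vocabulary:
#   acceptor     proton acceptor of the retinal Schiff base (BR Asp85,
#                ChR2 Asp253)
#   donor        proton donor during reprotonation (BR Asp96, ChR2 Asp156)
#   stabilizer   stabilises the acceptor (BR Thr89 hydrogen-bonds Asp85;
#                ChR2 Arg120 stabilises the acceptor and gates ion movement)
#   pocket       retinal-binding-pocket residue (BR Thr90)
#   dcGate       cysteine of the DC gate (ChR2 Cys128)
#   release1/2   proton-release group towards the extracellular side
#                (BR Glu194 / Glu204)
#   counterion   counterion of the Schiff base (BR Asp212)
#   attachment   retinal-binding lysine in helix 7 (BR Lys216, ChR2 Lys257)
#   tuner        spectral-tuning residue (proteorhodopsin position 105)
#   metal1/2     metal-binding aspartates of a class III cyclase
#   substrate    substrate-specifying residue (Glu for GTP, Lys for ATP)
#   transition1/2 transition-state stabilising residues (Asn, Arg)

.schemeDef <- function(name, roles, positions, expected) {
  methods::new("ReferenceScheme",
    name = name,
    scaffold = NA_character_,
    keyPositions = data.frame(
      role = roles,
      position = as.integer(positions),
      refPosition = as.integer(positions),
      expected = I(expected),
      stringsAsFactors = FALSE))
}

.BUILTIN_SCHEMES <- list(
  BR = list(
    roles = c("acceptor", "stabilizer", "pocket", "donor",
              "release1", "release2", "counterion", "attachment"),
    positions = c(85L, 89L, 90L, 96L, 194L, 204L, 212L, 216L),
    expected = list(c("D", "E"), c("S", "T"), "T", "D",
                    c("D", "E"), c("D", "E"), "D", "K")),
  ChR2 = list(
    roles = c("stabilizer", "dcGate", "donor", "acceptor", "attachment"),
    positions = c(120L, 128L, 156L, 253L, 257L),
    expected = list("R", "C", "D", c("D", "E"), "K")),
  GPR = list(
    roles = "tuner",
    positions = 105L,
    expected = list(c("L", "Q"))),
  CYC = list(
    roles = c("metal1", "metal2", "substrate", "transition1", "transition2"),
    positions = c(45L, 89L, 101L, 145L, 149L),
    expected = list("D", "D", c("E", "K"), "N", "R"))
)

#' Built-in reference schemes
#'
#' Returns the key-position scheme for one of the four built-in references:
#' \describe{
#'   \item{\code{"BR"}}{bacteriorhodopsin ion-pumping scheme; positions 85,
#'     89, 90, 96, 194, 204, 212, 216.}
#'   \item{\code{"ChR2"}}{channelrhodopsin-2 channel scheme; positions 253
#'     (acceptor), 156 (donor), 128 (DC-gate cysteine), 120 (acceptor
#'     stabiliser), 257 (retinal lysine).}
#'   \item{\code{"GPR"}}{green proteorhodopsin spectral-tuning scheme;
#'     position 105.}
#'   \item{\code{"CYC"}}{canonical class III cyclase catalytic scheme: two
#'     metal-binding aspartates, the substrate-specifying residue and the two
#'     transition-state stabilising residues, numbered on the packaged
#'     synthetic cyclase reference row.}
#' }
#'
#' Built-in schemes carry no scaffold sequence; supply one (a real reference
#' FASTA or a synthetic scaffold from \code{\link{makeScaffold}}) before
#' alignment-based mapping.
#'
#' @param name scheme name.
#' @param scaffold optional scaffold amino-acid string to attach (positions
#'   are kept in reference numbering; use \code{\link{makeScaffold}} when the
#'   scaffold uses its own coordinates).
#' @return a \code{\link{ReferenceScheme}}.
#' @examples
#' referenceScheme("BR")
#' @export
referenceScheme <- function(name = c("BR", "ChR2", "GPR", "CYC"),
                            scaffold = NA_character_) {
  name <- match.arg(name)
  def <- .BUILTIN_SCHEMES[[name]]
  sch <- .schemeDef(name, def$roles, def$positions, def$expected)
  if (!is.na(scaffold)) {
    scaffold <- toupper(scaffold)
    .checkResidues(scaffold, paste0(name, " scaffold"))
    sch@scaffold <- scaffold
    methods::validObject(sch)
  }
  sch
}

# Role name for a published reference position within a scheme.
.roleForPosition <- function(scheme, position) {
  kp <- scheme@keyPositions
  i <- match(as.integer(position), kp$refPosition)
  if (is.na(i))
    stop(sprintf("position %s is not a key position of scheme %s",
                 position, scheme@name))
  kp$role[i]
}

# Expected residue set for a role.
.expectedFor <- function(scheme, role) {
  kp <- scheme@keyPositions
  kp$expected[[match(role, kp$role)]]
}
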