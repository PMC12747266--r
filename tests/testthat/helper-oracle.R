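# Independent chemistry oracle: computes descriptors by calling RDKit
# directly from the test suite (its own inline program), bypassing the
# package's bridge and registry code path entirely.

oracle_panel <- c(
  "CCO", "c1ccccc1", "c1ccncc1", "C[C@H](N)C(=O)O",
  "CC(=O)Oc1ccccc1C(=O)O",              # aspirin
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",         # caffeine
  "CC(C)Cc1ccc(C(C)C(=O)O)cc1",         # ibuprofen
  "CC(=O)Nc1ccc(O)cc1",                 # paracetamol
  "c1ccc2ccccc2c1", "c1ccoc1", "c1ccsc1",
  "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1", "OC(=O)c1ccccc1",
  "C1CCCCC1", "C1CCNCC1", "C1COCCN1",
  "Clc1ccccc1", "FC(F)(F)c1ccccc1", "N#Cc1ccccc1",
  "OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O",  # glucopyranose
  "CN1CCC[C@H]1c1cccnc1",               # nicotine
  "C1CCC2(CC1)CCCCC2",                  # spiro[5.5]undecane
  "C1CC2CCC1C2"                         # norbornane
)

oracle_physchem <- function(smiles) {
  script <- '
import sys, json
from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors as D, rdMolDescriptors as RD
RDLogger.DisableLog("rdApp.*")
rows = []
for smi in json.load(open(sys.argv[1])):
    m = Chem.MolFromSmiles(smi)
    rows.append([
        D.MolWt(m), D.MolLogP(m), D.TPSA(m), D.NumHDonors(m), D.NumHAcceptors(m),
        D.NumRotatableBonds(m), D.NumAromaticRings(m), D.NumAliphaticRings(m),
        D.NumSaturatedRings(m), D.RingCount(m), D.FractionCSP3(m),
        D.HeavyAtomCount(m), RD.CalcNumAtomStereoCenters(m),
        Chem.GetFormalCharge(m), D.NumHeteroatoms(m), D.NumValenceElectrons(m),
        D.MolMR(m), D.Kappa1(m), D.Kappa2(m), D.Kappa3(m), D.BertzCT(m),
        RD.CalcNumBridgeheadAtoms(m), RD.CalcNumSpiroAtoms(m),
        D.NumAromaticHeterocycles(m), D.NumSaturatedHeterocycles(m),
        D.NumAliphaticHeterocycles(m), RD.CalcNumAmideBonds(m),
        D.HallKierAlpha(m), D.LabuteASA(m), D.BalabanJ(m), D.Chi0v(m), D.Chi1v(m),
    ])
json.dump(rows, open(sys.argv[2], "w"))
'
  sf <- tempfile(fileext = ".py")
  inf <- tempfile(fileext = ".json")
  outf <- tempfile(fileext = ".json")
  on.exit(unlink(c(sf, inf, outf)))
  writeLines(script, sf)
  jsonlite::write_json(smiles, inf)
  status <- system2("python", c(sf, inf, outf), stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0L)
  out <- do.call(rbind, lapply(jsonlite::read_json(outf),
                               function(r) as.numeric(unlist(r))))
  rownames(out) <- smiles
  out
}

# Morgan fingerprint oracle, again via a direct RDKit call.
oracle_fingerprint <- function(smiles, nbits = 512L, radius = 2L) {
  script <- sprintf('
import sys, json
from rdkit import Chem, RDLogger
from rdkit.Chem import rdMolDescriptors as RD
RDLogger.DisableLog("rdApp.*")
out = []
for smi in json.load(open(sys.argv[1])):
    fp = RD.GetMorganFingerprintAsBitVect(Chem.MolFromSmiles(smi), %d, nBits=%d)
    out.append(list(fp.GetOnBits()))
json.dump(out, open(sys.argv[2], "w"))
', radius, nbits)
  sf <- tempfile(fileext = ".py")
  inf <- tempfile(fileext = ".json")
  outf <- tempfile(fileext = ".json")
  on.exit(unlink(c(sf, inf, outf)))
  writeLines(script, sf)
  jsonlite::write_json(smiles, inf)
  status <- system2("python", c(sf, inf, outf), stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0L)
  mat <- matrix(0L, length(smiles), nbits)
  bits <- jsonlite::read_json(outf)
  for (i in seq_along(bits)) mat[i, as.integer(unlist(bits[[i]])) + 1L] <- 1L
  mat
}

relative_match <- function(x, y, signif_digits = 6) {
  scale <- pmax(abs(x), abs(y))
  diff <- abs(x - y)
  diff <= 10^(-signif_digits) * pmax(scale, 1e-12) | (x == y)
}
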