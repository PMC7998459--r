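# Built-in reference set: published MSDIN precursor rows (leader / core /
# recognition and the reported monoisotopic mass of the unmodified cyclic
# core, or of the mature toxin for the classical toxin genes) from four
# lethal Amanita species, plus the reported set of cyclic peptides detected
# by LC-HRMS/MS. Alignment gap characters in some recognition sequences
# were removed. These rows power the self-verification table, the mining
# fixtures and the synthetic-data templates.

.MSDIN_ROWS <- c(
  # species | leader | core | recognition | reported_mass | toxin | expressed
  "A. rimosa|MSDINSTRLP|IWGIGCNP|SVGDEVTALLTRGEA|918.3541|alpha-amanitin|NA",
  "A. rimosa|MSDINATRLP|IWGIGCNP|SVGDEVTALLASGEA|918.3541|alpha-amanitin|NA",
  "A. rimosa|MSDINATRLP|IWGIGCDP|CVGDDVAALTTRGEA|919.3382|beta-amanitin|NA",
  "A. rimosa|MSDINATRVP|AWLVDCP|CVGDDISRLLTRGEK|846.3217|phallacidin|NA",
  "A. rimosa|MSDINATRLP|AWDSKHP|CVGDDVSRLLTRGE|821.3820||NA",
  "A. rimosa|MSDINATRLP|AWDSKHP|CVGDDISRLLTRGE|821.3820||NA",
  "A. rimosa|MSDINATRVP|AWLAECP|CVGDDISHLLTRGE|770.3421||NA",
  "A. rimosa|MSDINASRLP|FFIIIVKP|CGNPYVSDDVNSTLTRGE|957.6052||NA",
  "A. rimosa|MSDINTSRLP|FIPLGIITILP|CVSDDVNTTITRGD|1177.7475||NA",
  "A. rimosa|MSDINTACLP|FLFPVIPP|CLSEDANVVVLNSGE|910.5317||NA",
  "A. rimosa|MSDINVTRLP|FFPIVFIPP|CI|1057.6000||NA",
  "A. rimosa|MSDINIARLP|IFWFIYFP|CVGDDVDNTLSRGE|1113.5688||NA",
  "A. rimosa|MSDINVTRLP|IFLIMFIPP|CIGDDAASILKQGE|1071.6191||NA",
  "A. rimosa|MSDINTSCLP|IFIAFPIPP|CVSDDIQTVLTRGE|995.5844||NA",
  "A. rimosa|MSDTNTACLP|IFIAFPIPP|CVSDDIQTVLTRGE|995.5844||NA",
  "A. rimosa|MSDINASRLP|ILKKPWAP|SVCDDVNSTLTRGE|933.5800||NA",
  "A. rimosa|MSDINVARLP|ISDPTAYP|CVGDDIQAVVKRGE|844.3967||NA",
  "A. rimosa|MSDINATRLP|IIIVLGLIIP|LCVSDIEMILTRGE|1044.7311||NA",
  "A. rimosa|MSDINASRLP|IILAPIIP|CISDDVNTTLTCAE|830.5630||NA",
  "A. rimosa|MSDINTTGLP|HFYNLMPP|CFSDDTGMVLVRGE|999.4637||NA",
  "A. rimosa|MSDINATRLP|HPFPLGLQP|CAGDVDNFTLIKGE|986.5338||NA",
  "A. rimosa|MSDINASCLP|LILVANGMAYV|SDDVSPTLTRGE|1144.6315||NA",
  "A. rimosa|MSDINTARLP|SYIPFPPP|CLSEDTNAVLMLGE|898.4589||NA",
  "A. rimosa|MSDINTARLP|SYIPFPPP|CLSEDTNAVLMLGE|898.4589||NA",
  "A. rimosa|MSDINTSRFP|SYGYRAFP|CVGDDVEMVLMHGE|941.4396||NA",
  "A. rimosa|MSDINVTRLP|VLVFIFFLP|CISDDAASIIKLGE|1075.6470||NA",
  "A. rimosa|MSDIDTTRLP|LILFTLQP|SIGDDVNPTLTRGEK|925.5637||NA",
  "A. rimosa|MSDIHAARLP|FPTRPVFP|SAGDDMIEVVLGRGE|941.5123||NA",
  "A. rimosa|MSDNNAARLP|FYFYLGIP|SDDAHPILTRGERLA|1000.5058||NA",
  "A. rimosa|MSDTNTARLP|ILFIQLEIP|CISDDVHPVLTRGE|1066.6427||NA",
  "A. rimosa|MSDVNTTRLP|FNFFRFPYP|CICDDSEKVLELGE|1215.5866||NA",
  "A. rimosa|MSEINTARFP|NHGHRTIP|CVGDDIEMVLMHGE|912.4678||NA",
  "A. rimosa|MSEINTSRLP|LVFIPPYFAP|CVSDDIQMVLTLGE|1144.6321||NA",
  "A. rimosa|MFDMNTTCLP|GFIIYAYV|GDDVNHTLTRGE|926.4902||NA",
  "A. rimosa|MLDINTARLP|FSLPTFPP|CVSDEIDVVLKRGE|886.4589||NA",
  "A. rimosa|MLDINATRFP|LGRPTHLP|CVGDDVNYIL|871.5028||NA",
  "A. rimosa|MTDINDARLP|ILLLIFFWIP|CANDDDENILNRG|1255.7733||NA",
  "A. rimosa|MTDINDTRLP|FVWILWLWLA|CVGDDTSILNRGE|1327.7481||NA",
  "A. rimosa|MPDINVTRLP|LLIIVLLTP|CISDDNNILNRGK|975.6732||NA",
  "A. exitialis|MSDINATRLP|IWGIGCNP|CVGDDVTSVLTRGEA|918.3541|alpha-amanitin|NA",
  "A. exitialis|MSDINATRLP|IWGIGCDP|CVGDDVTALLTRGEA|919.3382|beta-amanitin|NA",
  "A. exitialis|MSDINATRLP|AWLVDCP|CVGDDVNRLLTRGE|846.3217|phallacidin|NA",
  "A. exitialis|MSDINATRLP|AWLTDCP|CVGDDVNRLLTRGE|786.3371||NA",
  "A. exitialis|MSDINTTRLP|FVFVASPP|CVGDDIAMVLTRGE|844.4483||NA",
  "A. exitialis|MSDINTARLP|FIWVFGIP|GDDIGTVLTRGEK|959.5269||NA",
  "A. exitialis|MSDINLTRLP|GIIAIIP|CVGDDDDVNSTLTRGQ|677.4476||NA",
  "A. exitialis|MSDINATRLP|IILAPVIP|CISDDNDPTLTRGQ|816.5473||NA",
  "A. exitialis|MSDINTARLP|IPIPPFFFP|FVSDDIEIVLRRGEK|1055.5844||NA",
  "A. exitialis|MSDINTARLP|IPIPPFFFP|FVSDDIEIVLRRGEK|1055.5844||NA",
  "A. exitialis|MSDINATRLP|IGRPQLLP|CVGGDVNYILISGEK|874.5389||NA",
  "A. exitialis|MSDINPTRLP|IFWFIYFP|CVSDVDSTLTRGE|1113.5688||NA",
  "A. exitialis|MSDINTARLP|IYRPPFYALP|CVGDDIQAVLTRGE|1217.6597||NA",
  "A. exitialis|MSDINTARLP|IIWIIGNP|CVSDDVERILTRGE|906.5327||NA",
  "A. exitialis|MSDINVIRAP|LLILSILP|CVGDDIEVLRRGE|862.5892||NA",
  "A. exitialis|MSDINATRLP|LFFPPDFRPP|CVGDADNFTLTRGEK|1213.6284||NA",
  "A. exitialis|MSDINATRLP|LFFPPDFRPP|CVGDADNFTLTRGE|1213.6284||NA",
  "A. exitialis|MSDINVIRLP|SMLTILPP|CVSDDASNTLTRGE|852.4779||NA",
  "A. exitialis|MSDINTARLP|VFSLPVFFP|SDDIQAVLTRGE|1033.5637||NA",
  "A. exitialis|MSDINVTRLP|VFIFFFIPP|CVGDGTADIVRKGEK|1107.6157||NA",
  "A. exitialis|MSDINATRLP|VWIGYSP|CVGDDCIALLTRGE|802.4014||NA",
  "A. exitialis|MSDINATRLP|VWIGYSP|CVGDDCIALLTRGE|802.4014||NA",
  "A. exitialis|MTDINDTRLP|FIWLLWIWLP|SVGDDNNILNRGEE|1367.7794||NA",
  "A. subjunquillea|MSDINATCLP|IWGIGCNP|CVGDEVAALLTRGEALC|918.3541|alpha-amanitin|TRUE",
  "A. subjunquillea|MSDINATRLP|IWGIGCDP|CVGDEVTALLTRGEALC|919.3382|beta-amanitin|TRUE",
  "A. subjunquillea|MSDINATRLP|IWGIGCDP|CIGDDVTALLTRGEALC|919.3382|beta-amanitin|TRUE",
  "A. subjunquillea|MSDINATRLP|AWLATCP|CAGDDVNPTLTRGESLC|788.3160|phalloidin|TRUE",
  "A. subjunquillea|MSDINATRLP|AWLVDCP|CVGDDINRRVVSAFAC|846.3217|phallacidin|TRUE",
  "A. subjunquillea|MSDMNATRLP|LIQRPFAP|CVSDDVDFALIRRCALVYAESSV|922.5389||TRUE",
  "A. subjunquillea|MSDINTARLP|HFASFIPP|CIGDDIEMVLKRGESLC|896.4545||TRUE",
  "A. subjunquillea|MSDINTARLP|TFLPPLFVPP|CVSDDIEMVLTRGESLC|1108.6321|CylG1|TRUE",
  "A. subjunquillea|MSDINATRLP|LNILPFMLPP|CVGDDVNPTLTRGEDLC|1135.6464||TRUE",
  "A. subjunquillea|MSDMNATRLP|LIQRPYAP|CVSDDVNSPLTRGESLC|938.5338||TRUE",
  "A. subjunquillea|MSDINTARLP|IGRPESIP|CVGDDIEMILERGQKLC|849.4709||TRUE",
  "A. subjunquillea|MSDINTARLP|LRLPPFMIPP|CVGDDIGMVLTRGENLC|1161.6733||TRUE",
  "A. subjunquillea|MSDVNATRLP|FNFFRFPYP|CIGDDSASVLGLGESLC|1215.5866||TRUE",
  "A. subjunquillea|MSDINATRLP|SSVLPRP|CVGDVDNIILTSREKLC|736.4232||TRUE",
  "A. subjunquillea|MSDINTARLP|AFFPPFFIPP|CVSDDIEMVLTRGESLC|1160.6059|CylG2|TRUE",
  "A. subjunquillea|MSDINATRLP|IPILPIPP|YCSDDANTTLTLGESLC|840.5473||TRUE",
  "A. subjunquillea|MSDINATRLP|LFLLAALGIP|SDDADSTLTRGESLC|1008.6372||TRUE",
  "A. subjunquillea|MSDTNDARLP|LFFWFWFLWP|SVSDDIDSVLNRGEDLC|1469.7325||TRUE",
  "A. subjunquillea|MSDMNVARLP|ISDPTAYP|CVGGDIHAVLRRGE|844.3966||FALSE",
  "A. subjunquillea|MSDMNVARLP|ISDPTAYP|CVGGDIHAVLRRGE|844.3966||FALSE",
  "A. subjunquillea|MSDINVTCLP|FIFWFFWPP|CVGDDAASIIKGK|1267.6218||FALSE",
  "A. subjunquillea|MSDINAARLP|FIFPPFFIPP|CVSDDIEMVLTRGE|1202.6528||FALSE",
  "A. subjunquillea|MSDINTVCLP|LQKPWSRP|CVGDDIEMILERGE|992.5556||FALSE",
  "A. subjunquillea|MFDINITRLP|IFWFIYFP|CVGDDVTALLTRGE|1113.5689||FALSE"
)

.CYCLOPEPTIDE_ROWS <- c(
  # species | core | name | formula | theoretical_mz | measured_mz | delta_ppm
  "A. subjunquillea|TFLPPLFVPP|CylG1|C59H84N10O11|1109.6394|1109.6398|0.36",
  "A. subjunquillea|AFFPPFFIPP|CylG2|C65H80N10O10|1161.6132|1161.6161|2.50",
  "A. rimosa|ISDPTAYP|CylH1|C39H56N8O13|845.4039|845.4040|0.12",
  "A. rimosa|FIPLGIITILP|CylH2|C61H99N11O12|1178.7547|1178.7555|0.68",
  "A. rimosa|FPTRPVFP|CylH3|C48H67N11O9|942.5196|942.5191|0.53",
  "A. pallidorosea|EFIVFGIFP|CylI1|C56H75N9O11|1050.5658|1050.5694|3.43",
  "A. pallidorosea|FVIIPPFIFP|CylI2|C65H90N10O10|1171.6914|1171.6941|2.31",
  "A. pallidorosea|YFFNDHPP|CylI3|C51H59N11O12|1018.4417|1018.4421|0.39",
  "A. pallidorosea|TIHLFSAP|CylI4|C42H62N10O10|867.4723|867.4733|1.15",
  "A. pallidorosea|MHILAPPP|CylI5|C41H64N10O8S|857.4702|857.4714|1.40",
  "A. exitialis|FVFVASPP|CylJ1|C44H60N8O9|845.4556|845.4582|3.08",
  "A. exitialis|LFFPPDFRPP|CylJ2|C63H83N13O12|1214.6357|1214.6357|0.00",
  "A. exitialis|VFSLPVFFP|amanexitide|C56H75N9O10|1034.5709|1034.5734|2.42"
)

.parse_rows <- function(rows, cols) {
  m <- do.call(rbind, strsplit(rows, "|", fixed = TRUE))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

#' Reference MSDIN precursor table
#'
#' The published MSDIN precursor rows from *Amanita rimosa*, *A. exitialis*
#' and *A. subjunquillea*: 10-residue leader, 7-11 residue core, recognition
#' sequence, the reported monoisotopic mass (unmodified cyclic core, or the
#' mature toxin for the classical amatoxin/phallotoxin genes), and - for
#' *A. subjunquillea* - whether transcription was detected.
#'
#' @return A data.frame with columns `species`, `leader`, `core`,
#'   `recognition`, `reported_mass`, `toxin` (modified-toxin or cyclopeptide
#'   label, `NA` for plain rows) and `expressed` (logical, `NA` where no
#'   transcriptome was examined). One row per precursor gene copy (86 rows).
#' @export
msdin_reference <- function() {
  df <- .parse_rows(.MSDIN_ROWS, c("species", "leader", "core", "recognition",
                                   "reported_mass", "toxin", "expressed"))
  df$reported_mass <- as.numeric(df$reported_mass)
  df$toxin[df$toxin == ""] <- NA_character_
  df$expressed <- as.logical(df$expressed)
  df
}

#' Reference table of detected cyclic peptides
#'
#' The cyclic peptides confirmed by LC-HRMS and MS/MS in the four examined
#' species: core sequence, peptide name, neutral molecular formula, and the
#' reported theoretical/measured \[M+H\]+ m/z with their ppm discrepancy.
#'
#' @return A data.frame with columns `species`, `core`, `name`, `formula`,
#'   `theoretical_mz`, `measured_mz`, `delta_ppm` (13 rows).
#' @export
cyclopeptide_reference <- function() {
  df <- .parse_rows(.CYCLOPEPTIDE_ROWS,
                    c("species", "core", "name", "formula",
                      "theoretical_mz", "measured_mz", "delta_ppm"))
  for (cc in c("theoretical_mz", "measured_mz", "delta_ppm"))
    df[[cc]] <- as.numeric(df[[cc]])
  df
}

# toxin label -> modification state that the enumeration must contain
.TOXIN_STATES <- list(
  "alpha-amanitin" = list(n_hydroxyl = 4, sulfoxide = TRUE,  bridge = TRUE),
  "beta-amanitin"  = list(n_hydroxyl = 4, sulfoxide = TRUE,  bridge = TRUE),
  "phallacidin"    = list(n_hydroxyl = 4, sulfoxide = FALSE, bridge = TRUE),
  "phalloidin"     = list(n_hydroxyl = 3, sulfoxide = FALSE, bridge = TRUE)
)

#' Self-verification table of reference masses
#'
#' Recomputes, from the built-in reference precursor rows, the monoisotopic
#' mass of every unmodified cyclic core - and, for the classical toxin rows,
#' the best-matching modification state from the full enumeration - and
#' compares them with the reported values.
#'
#' @param digits Decimals for the printed masses (default 4).
#' @return A data.frame with columns `species`, `core`, `toxin`,
#'   `computed_mass`, `reported_mass`, `abs_error`, plus the modification
#'   state used (`n_hydroxyl`, `sulfoxide`, `bridge`; zeros for plain rows).
#' @export
toxin_table <- function(digits = 4) {
  ref <- msdin_reference()
  out <- lapply(seq_len(nrow(ref)), function(i) {
    core <- ref$core[i]
    lab <- ref$toxin[i]
    if (!is.na(lab) && lab %in% names(.TOXIN_STATES)) {
      st <- .TOXIN_STATES[[lab]]
    } else {
      st <- list(n_hydroxyl = 0, sulfoxide = FALSE, bridge = FALSE)
    }
    comp <- apply_modifications(peptide_composition(core, "cyclic"), core,
                                st$n_hydroxyl, st$sulfoxide, st$bridge)
    m <- monoisotopic_mass(comp)
    data.frame(species = ref$species[i], core = core, toxin = lab,
               n_hydroxyl = st$n_hydroxyl, sulfoxide = st$sulfoxide,
               bridge = st$bridge,
               computed_mass = round(m, digits),
               reported_mass = ref$reported_mass[i],
               abs_error = round(abs(m - ref$reported_mass[i]), digits),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
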