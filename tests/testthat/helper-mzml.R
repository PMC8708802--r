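# Minimal standalone mzML with one centroided spectrum and inline base64
# 64-bit float arrays — just enough for an independent reader to parse.
minimal_mzml <- function(mz, intensity) {
  enc <- function(v) {
    jsonlite::base64_enc(writeBin(as.numeric(v), raw(), size = 8,
                                  endian = "little"))
  }
  b_mz <- enc(mz); b_int <- enc(intensity)
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum"/>',
    '</fileContent></fileDescription>\n',
    '<run id="r1">\n<spectrumList count="1" defaultDataProcessingRef="dp1">\n',
    '<spectrum index="0" id="scan=1" defaultArrayLength="', length(mz), '">',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum"/>',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>',
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan"/>',
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="', nchar(b_mz), '">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<binary>', b_mz, '</binary></binaryDataArray>',
    '<binaryDataArray encodedLength="', nchar(b_int), '">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<binary>', b_int, '</binary></binaryDataArray>',
    '</binaryDataArrayList></spectrum>\n',
    '</spectrumList>\n</run>\n</mzML>\n')
}
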