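# Paths to the committed 20-protein fixture proteome (generated once by
# scripts/make_fixture.R with the package's own generator, seed 101).
fixture_path <- function(name) {
  system.file("extdata", "fixture", name, package = "lcrsurvey",
              mustWork = TRUE)
}

fixture_manifest <- function() {
  data.frame(proteome_id = "synth01", taxon = "phylum1",
             fasta = fixture_path("synth01.fasta"),
             pfamscan = fixture_path("pfamscan.txt"),
             tmhmm = fixture_path("tmhmm_short.txt"),
             signalp = fixture_path("signalp.txt"),
             stringsAsFactors = FALSE)
}

# small in-code FASTA writer for hand-built cases
write_tmp_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(entries), function(id)
    c(paste0(">", id), entries[[id]]))), path)
  path
}
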