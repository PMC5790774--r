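# Fixture changelog and transcription notes

All fixtures in this directory are manual transcriptions of printed source
tables (the upstream EST database is retired; no machine-readable copies
exist). Every deviation from the printed characters is listed here; nothing
was silently edited.

## th_regulators.tsv / .json (61-gene Th-subset regulator catalog)

- `IL12RB1` is printed with a trailing footnote asterisk (`IL12RB1*`);
  the asterisk is a footnote marker, not part of the symbol, and is dropped.
- Subset labels normalized to the canonical codes
  (`TH1 -> Th1`, `TFH -> Tfh`, ...); membership is unchanged.
- Housekeeping symbols `PRS27A` and `GADPH` are kept exactly as printed even
  though the standard symbols are RPS27A and GAPDH; see `gene_aliases.tsv`.
  The alias map is never applied silently.

## tissue_calls_human.tsv (gene x 32-tissue trichotomous call matrix)

- Tokens: blank cells in the print are stored as `-` (not expressed);
  `+` and `++` are stored verbatim.
- Row labels carry parenthetical subset annotations in print
  (e.g. `BCL6 (Tfh*)`, `GATA3 (Th2)`); the annotation is dropped and only
  the symbol kept.
- OCR-style symbol variants in the print were restored to the catalog
  symbols: `CCLL5 -> CCL15`, `L12RB1 -> IL12RB1`, `L13 -> IL13`,
  `IL7B -> IL17B`, `L10RB -> IL10RB`, `TBX21 (Thl) -> TBX21`.
- The HNF1A row's Liver cell is printed as `+ +` (split by a stray space);
  stored as `++`.
- The FOXP3 row is absent from the machine-extracted table although the
  surrounding narrative describes its profile explicitly ("expressed in
  trachea, thymus, spleen, mammary gland, lymph node, lung, eye, and blood;
  trachea highly expressed"). The row was RECONSTRUCTED from that sentence
  (`++` in trachea, `+` in the other seven named tissues, `-` elsewhere).
  It is the only reconstructed row.
- Tissue column headers are kept as printed, including the spellings
  "Prostrate" and "Umbilic chord".
- **Known text-vs-table discrepancy:** the narrative states BCL6 is
  "expressed in 28 tissues", but the printed matrix row contains 29
  non-blank cells (the high calls — adipose tissue, nerve, trachea — agree).
  The table is transcribed faithfully; counting over this fixture yields 29.
  All other narrative counts (GATA3 21/32; SPI1 16 expressed, 11 high;
  RORC 18; STAT3 31) agree with the transcription exactly.
- Genes from the 61-gene catalog with no row in the printed matrix:
  ACT1, IL23 (no database entry printed), IL21, IL25, CD28. They are simply
  absent here, not zero rows.

## mhc2_diff_mouse.tsv (14-gene MHC-II signed fold changes, 3 knockouts)

- The print shows `H2-Abl` and `Mrl`; the official symbols for the printed
  NCBI Gene IDs 14961 and 15064 are `H2-Ab1` and `Mr1` (lowercase-L/one OCR
  confusion). The corrected symbols are stored; see `gene_aliases.tsv`.
- Blank cells mean "not significantly changed" in the pre-gated source
  table and are stored as empty fields.

## gene_sets.gmt

- `cosignal_partial` is the partial co-signaling receptor panel named in
  the running text (LIGHT, 4-1BBL, CD48, B7-1, CD112, Galectin-9, B7-DC,
  HVEM). The full 28-gene panel exists only as a figure and is NOT
  machine-readable; this set must not be presented as complete (the GMT
  description carries the same warning).
- `housekeeping_human` keeps the printed spellings PRS27A and GADPH.
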