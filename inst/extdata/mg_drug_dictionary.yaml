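# Target-drug dictionary: complement C5 inhibitors and FcRn inhibitors
# approved for generalized myasthenia gravis. Approval dates are the FDA
# approvals for the MG indication; reports are counted from these dates.
eculizumab:
  synonyms: [eculizumab, Soliris]
  approval: "20171023"
ravulizumab:
  synonyms: [ravulizumab, ravulizumab-cwvz, Ultomiris]
  approval: "20220427"
zilucoplan:
  synonyms: [zilucoplan, Zilbrysq]
  approval: "20231017"
efgartigimod:
  synonyms: [efgartigimod, efgartigimod alfa, efgartigimod alfa-fcab, Vyvgart, Vyvgart Hytrulo]
  approval: "20211217"
rozanolixizumab:
  synonyms: [rozanolixizumab, rozanolixizumab-noli, Rystiggo]
  approval: "20230626"
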