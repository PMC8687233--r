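<?xml version="1.0" encoding="UTF-8"?>
<!-- synthetic toy pathway in KGML layout, for examples and tests -->
<pathway name="path:syn00001" org="syn" number="00001" title="synthetic toy signalling pathway">
  <entry id="1" name="GENE_A" type="gene"/>
  <entry id="2" name="GENE_B GENE_C" type="gene"/>
  <entry id="3" name="GENE_D" type="gene"/>
  <entry id="4" name="cpd:C00001" type="compound"/>
  <relation entry1="1" entry2="2" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="2" entry2="3" type="GErel">
    <subtype name="repression" value="--|"/>
  </relation>
  <relation entry1="1" entry2="4" type="PCrel">
    <subtype name="binding/association" value="---"/>
  </relation>
</pathway>
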