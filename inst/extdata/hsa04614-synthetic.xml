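<?xml version="1.0"?>
<!-- Synthetic, hand-built fragment of the human renin-angiotensin pathway
     (hsa04614) for offline testing: a small subset of real gene entries
     with invented layout coordinates. NOT the KEGG-distributed KGML. -->
<pathway name="path:hsa04614" org="hsa" number="04614"
         title="Renin-angiotensin system (synthetic fragment)"
         image="hsa04614.png">
  <entry id="1" name="hsa:183" type="gene">
    <graphics name="AGT, ANHU, SERPINA8" type="rectangle" x="120" y="80" width="46" height="17"/>
  </entry>
  <entry id="2" name="hsa:5972" type="gene">
    <graphics name="REN, HNFJ2" type="rectangle" x="220" y="80" width="46" height="17"/>
  </entry>
  <entry id="3" name="hsa:1636" type="gene">
    <graphics name="ACE, ACE1, CD143, DCP" type="rectangle" x="320" y="80" width="46" height="17"/>
  </entry>
  <entry id="4" name="hsa:59272" type="gene">
    <graphics name="ACE2, ACEH" type="rectangle" x="320" y="140" width="46" height="17"/>
  </entry>
  <entry id="5" name="hsa:185" type="gene">
    <graphics name="AGTR1, AG2S, AGTR1B" type="rectangle" x="520" y="80" width="46" height="17"/>
  </entry>
  <entry id="6" name="hsa:186" type="gene">
    <graphics name="AGTR2, AT2" type="rectangle" x="520" y="140" width="46" height="17"/>
  </entry>
  <entry id="7" name="hsa:1359" type="gene">
    <graphics name="CPA3, MC-CPA" type="rectangle" x="220" y="200" width="46" height="17"/>
  </entry>
  <entry id="8" name="hsa:1511" type="gene">
    <graphics name="CTSG, CG" type="rectangle" x="120" y="200" width="46" height="17"/>
  </entry>
  <entry id="9" name="cpd:C02135" type="compound">
    <graphics name="Angiotensin II" type="circle" x="420" y="110" width="8" height="8"/>
  </entry>
  <entry id="10" name="path:hsa04610" type="map">
    <graphics name="Complement and coagulation cascades" type="roundrectangle" x="120" y="300" width="110" height="34"/>
  </entry>
  <relation entry1="1" entry2="2" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="2" entry2="3" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="3" entry2="5" type="PPrel">
    <subtype name="compound" value="9"/>
  </relation>
  <relation entry1="7" entry2="4" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="8" entry2="5" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
</pathway>
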