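<?xml version="1.0" encoding="UTF-8"?>
<!-- hand-written two-module toy, producer side: one transcription unit
     emitting mRNA_X into the cytoplasm; deliberately free of tool
     annotations to exercise tolerant reading -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:comp="http://www.sbml.org/sbml/level3/version1/comp/version1"
      level="3" version="1" comp:required="true">
  <model id="TU_X">
    <listOfCompartments>
      <compartment id="nucleus" size="1" constant="true"/>
      <compartment id="cytoplasm" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="mRNA_X" compartment="cytoplasm" initialAmount="0"
               hasOnlySubstanceUnits="true" boundaryCondition="false"
               constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="transcription_mRNA_X" reversible="false" fast="false">
        <listOfProducts>
          <speciesReference species="mRNA_X" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <ci>k</ci>
          </math>
          <listOfLocalParameters>
            <localParameter id="k" value="0.01"/>
          </listOfLocalParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
    <comp:listOfPorts>
      <comp:port comp:id="port_mRNA_X" comp:idRef="mRNA_X"/>
    </comp:listOfPorts>
  </model>
</sbml>
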