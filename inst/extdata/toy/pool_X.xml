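<?xml version="1.0" encoding="UTF-8"?>
<!-- hand-written two-module toy, consumer side: translation of mRNA_X into
     protein X with first-order decays, all mass action -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:comp="http://www.sbml.org/sbml/level3/version1/comp/version1"
      level="3" version="1" comp:required="true">
  <model id="pool_X">
    <listOfCompartments>
      <compartment id="cytoplasm" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="mRNA_X" compartment="cytoplasm" initialAmount="0"
               hasOnlySubstanceUnits="true" boundaryCondition="false"
               constant="false"/>
      <species id="X" compartment="cytoplasm" initialAmount="0"
               hasOnlySubstanceUnits="true" boundaryCondition="false"
               constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="translation_X" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="mRNA_X" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="mRNA_X" stoichiometry="1" constant="true"/>
          <speciesReference species="X" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>k</ci><ci>mRNA_X</ci></apply>
          </math>
          <listOfLocalParameters>
            <localParameter id="k" value="0.05"/>
          </listOfLocalParameters>
        </kineticLaw>
      </reaction>
      <reaction id="decay_mRNA_X" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="mRNA_X" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>k</ci><ci>mRNA_X</ci></apply>
          </math>
          <listOfLocalParameters>
            <localParameter id="k" value="0.0005"/>
          </listOfLocalParameters>
        </kineticLaw>
      </reaction>
      <reaction id="decay_X" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="X" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>k</ci><ci>X</ci></apply>
          </math>
          <listOfLocalParameters>
            <localParameter id="k" value="0.0001"/>
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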