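<?xml version="1.0" encoding="utf-8"?>
<!-- CellML 1.1 encoding of the package's built-in three-species toy
     pathway (source -> A -> B -> C -> sink, first-order mass action);
     used to exercise the CellML importer. -->
<model name="toy" xmlns="http://www.cellml.org/cellml/1.1#">
  <component name="environment">
    <variable name="time" units="second"/>
  </component>
  <component name="pathway">
    <variable name="A" units="micromolar" initial_value="0"/>
    <variable name="B" units="micromolar" initial_value="0"/>
    <variable name="C" units="micromolar" initial_value="0"/>
    <variable name="k1" units="flux" initial_value="0"/>
    <variable name="k2" units="first_order_rate_constant" initial_value="1"/>
    <variable name="k3" units="first_order_rate_constant" initial_value="10"/>
    <variable name="k4" units="first_order_rate_constant" initial_value="1"/>
    <math xmlns="http://www.w3.org/1998/Math/MathML">
      <apply><eq/>
        <apply><diff/><bvar><ci>time</ci></bvar><ci>A</ci></apply>
        <apply><minus/><ci>k1</ci><apply><times/><ci>k2</ci><ci>A</ci></apply></apply>
      </apply>
      <apply><eq/>
        <apply><diff/><bvar><ci>time</ci></bvar><ci>B</ci></apply>
        <apply><minus/>
          <apply><times/><ci>k2</ci><ci>A</ci></apply>
          <apply><times/><ci>k3</ci><ci>B</ci></apply>
        </apply>
      </apply>
      <apply><eq/>
        <apply><diff/><bvar><ci>time</ci></bvar><ci>C</ci></apply>
        <apply><minus/>
          <apply><times/><ci>k3</ci><ci>B</ci></apply>
          <apply><times/><ci>k4</ci><ci>C</ci></apply>
        </apply>
      </apply>
    </math>
  </component>
</model>
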