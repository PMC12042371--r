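"from","to","relation"
"Brazil-Atlantic","Andes-North","non-adjacent"
"Brazil-Boreal","Andes-North","adjacent-land"
"Brazil-South","Andes-North","adjacent-land"
"Caribbean","Andes-North","across-water"
"Mesoamerica","Andes-North","non-adjacent"
"Mexican-Transition-Zone","Andes-North","non-adjacent"
"Pacific","Andes-North","adjacent-land"
"Nearctic","Andes-North","non-adjacent"
"Asia","Andes-North","non-adjacent"
"Andes-North","Brazil-Atlantic","non-adjacent"
"Brazil-Boreal","Brazil-Atlantic","non-adjacent"
"Brazil-South","Brazil-Atlantic","adjacent-land"
"Caribbean","Brazil-Atlantic","across-water"
"Mesoamerica","Brazil-Atlantic","non-adjacent"
"Mexican-Transition-Zone","Brazil-Atlantic","non-adjacent"
"Pacific","Brazil-Atlantic","non-adjacent"
"Nearctic","Brazil-Atlantic","non-adjacent"
"Asia","Brazil-Atlantic","non-adjacent"
"Andes-North","Brazil-Boreal","adjacent-land"
"Brazil-Atlantic","Brazil-Boreal","non-adjacent"
"Brazil-South","Brazil-Boreal","adjacent-land"
"Caribbean","Brazil-Boreal","across-water"
"Mesoamerica","Brazil-Boreal","non-adjacent"
"Mexican-Transition-Zone","Brazil-Boreal","non-adjacent"
"Pacific","Brazil-Boreal","non-adjacent"
"Nearctic","Brazil-Boreal","non-adjacent"
"Asia","Brazil-Boreal","non-adjacent"
"Andes-North","Brazil-South","adjacent-land"
"Brazil-Atlantic","Brazil-South","adjacent-land"
"Brazil-Boreal","Brazil-South","adjacent-land"
"Caribbean","Brazil-South","across-water"
"Mesoamerica","Brazil-South","non-adjacent"
"Mexican-Transition-Zone","Brazil-South","non-adjacent"
"Pacific","Brazil-South","non-adjacent"
"Nearctic","Brazil-South","non-adjacent"
"Asia","Brazil-South","non-adjacent"
"Andes-North","Caribbean","across-water"
"Brazil-Atlantic","Caribbean","across-water"
"Brazil-Boreal","Caribbean","across-water"
"Brazil-South","Caribbean","across-water"
"Mesoamerica","Caribbean","across-water"
"Mexican-Transition-Zone","Caribbean","across-water"
"Pacific","Caribbean","across-water"
"Nearctic","Caribbean","across-water"
"Asia","Caribbean","across-water"
"Andes-North","Mesoamerica","non-adjacent"
"Brazil-Atlantic","Mesoamerica","non-adjacent"
"Brazil-Boreal","Mesoamerica","non-adjacent"
"Brazil-South","Mesoamerica","non-adjacent"
"Caribbean","Mesoamerica","across-water"
"Mexican-Transition-Zone","Mesoamerica","adjacent-land"
"Pacific","Mesoamerica","adjacent-land"
"Nearctic","Mesoamerica","non-adjacent"
"Asia","Mesoamerica","non-adjacent"
"Andes-North","Mexican-Transition-Zone","non-adjacent"
"Brazil-Atlantic","Mexican-Transition-Zone","non-adjacent"
"Brazil-Boreal","Mexican-Transition-Zone","non-adjacent"
"Brazil-South","Mexican-Transition-Zone","non-adjacent"
"Caribbean","Mexican-Transition-Zone","across-water"
"Mesoamerica","Mexican-Transition-Zone","adjacent-land"
"Pacific","Mexican-Transition-Zone","non-adjacent"
"Nearctic","Mexican-Transition-Zone","adjacent-land"
"Asia","Mexican-Transition-Zone","non-adjacent"
"Andes-North","Pacific","adjacent-land"
"Brazil-Atlantic","Pacific","non-adjacent"
"Brazil-Boreal","Pacific","non-adjacent"
"Brazil-South","Pacific","non-adjacent"
"Caribbean","Pacific","across-water"
"Mesoamerica","Pacific","adjacent-land"
"Mexican-Transition-Zone","Pacific","non-adjacent"
"Nearctic","Pacific","non-adjacent"
"Asia","Pacific","non-adjacent"
"Andes-North","Nearctic","non-adjacent"
"Brazil-Atlantic","Nearctic","non-adjacent"
"Brazil-Boreal","Nearctic","non-adjacent"
"Brazil-South","Nearctic","non-adjacent"
"Caribbean","Nearctic","across-water"
"Mesoamerica","Nearctic","non-adjacent"
"Mexican-Transition-Zone","Nearctic","adjacent-land"
"Pacific","Nearctic","non-adjacent"
"Asia","Nearctic","across-water"
"Andes-North","Asia","non-adjacent"
"Brazil-Atlantic","Asia","non-adjacent"
"Brazil-Boreal","Asia","non-adjacent"
"Brazil-South","Asia","non-adjacent"
"Caribbean","Asia","across-water"
"Mesoamerica","Asia","non-adjacent"
"Mexican-Transition-Zone","Asia","non-adjacent"
"Pacific","Asia","non-adjacent"
"Nearctic","Asia","across-water"
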