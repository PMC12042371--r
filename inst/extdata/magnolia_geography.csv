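"taxon","areas"
"Magnolia_henryi","Asia"
"Magnolia_kachirachirai","Asia"
"Magnolia_septentrionalis","Asia"
"Magnolia_grandis","Asia"
"Magnolia_foveolata","Asia"
"Magnolia_obovata","Asia"
"Magnolia_biondii","Asia"
"Magnolia_grandiflora","Nearctic"
"Magnolia_macrophylla","Nearctic"
"Magnolia_acuminata","Nearctic"
"Liriodendron_tulipifera","Nearctic"
"Magnolia_dealbata","Mexican-Transition-Zone"
"Magnolia_rzedowskiana","Mexican-Transition-Zone"
"Magnolia_vovidesii","Mexican-Transition-Zone"
"Magnolia_iltisiana","Mexican-Transition-Zone"
"Magnolia_ofeliae","Mexican-Transition-Zone"
"Magnolia_zoquepopolucae","Mexican-Transition-Zone"
"Magnolia_mexicana","Mesoamerica,Mexican-Transition-Zone"
"Magnolia_panamensis","Mesoamerica"
"Magnolia_sharpii","Mesoamerica"
"Magnolia_allenii","Mesoamerica"
"Magnolia_lacandonica","Mesoamerica"
"Magnolia_macrocarpa","Mesoamerica"
"Magnolia_wetteri","Mesoamerica"
"Magnolia_emarginata","Caribbean"
"Magnolia_splendens","Caribbean"
"Magnolia_dodecapetala","Caribbean"
"Magnolia_bankardiorum","Andes-North"
"Magnolia_coronata","Andes-North"
"Magnolia_jaenensis","Andes-North"
"Magnolia_kichuana","Andes-North"
"Magnolia_pastazaensis","Andes-North"
"Magnolia_virolinensis","Andes-North"
"Magnolia_zamorana","Andes-North"
"Magnolia_silvioi","Pacific"
"Magnolia_wolfii","Pacific"
"Magnolia_ptaritepuiana","Brazil-Boreal"
"Magnolia_rimachii","Brazil-Boreal"
"Magnolia_ovata","Brazil-Atlantic,Brazil-South"
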