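39 10 (Andes-North Brazil-Atlantic Brazil-Boreal Brazil-South Caribbean Mesoamerica Mexican-Transition-Zone Pacific Nearctic Asia)
Magnolia_henryi 0000000001
Magnolia_kachirachirai 0000000001
Magnolia_septentrionalis 0000000001
Magnolia_grandis 0000000001
Magnolia_foveolata 0000000001
Magnolia_obovata 0000000001
Magnolia_biondii 0000000001
Magnolia_grandiflora 0000000010
Magnolia_macrophylla 0000000010
Magnolia_acuminata 0000000010
Liriodendron_tulipifera 0000000010
Magnolia_dealbata 0000001000
Magnolia_rzedowskiana 0000001000
Magnolia_vovidesii 0000001000
Magnolia_iltisiana 0000001000
Magnolia_ofeliae 0000001000
Magnolia_zoquepopolucae 0000001000
Magnolia_mexicana 0000011000
Magnolia_panamensis 0000010000
Magnolia_sharpii 0000010000
Magnolia_allenii 0000010000
Magnolia_lacandonica 0000010000
Magnolia_macrocarpa 0000010000
Magnolia_wetteri 0000010000
Magnolia_emarginata 0000100000
Magnolia_splendens 0000100000
Magnolia_dodecapetala 0000100000
Magnolia_bankardiorum 1000000000
Magnolia_coronata 1000000000
Magnolia_jaenensis 1000000000
Magnolia_kichuana 1000000000
Magnolia_pastazaensis 1000000000
Magnolia_virolinensis 1000000000
Magnolia_zamorana 1000000000
Magnolia_silvioi 0000000100
Magnolia_wolfii 0000000100
Magnolia_ptaritepuiana 0010000000
Magnolia_rimachii 0010000000
Magnolia_ovata 0101000000
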