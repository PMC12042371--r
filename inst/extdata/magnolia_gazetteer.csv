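taxon,locality,areas
Magnolia_henryi,"South China Botanical Garden, China",Asia
Magnolia_kachirachirai,"Kunming Botanical Garden, China (native: Taiwan)",Asia
Magnolia_septentrionalis,"South China Botanical Garden, China",Asia
Magnolia_dealbata,"Chollipo arboretum, South Korea (native: Mexico, cloud forest)",Mexican-Transition-Zone
Magnolia_grandiflora,"Florida, USA",Nearctic
Magnolia_macrophylla,"Chollipo Arboretum, Rep. of Korea (native: SE USA)",Nearctic
Magnolia_rzedowskiana,"San Luis Potosi, Mexico",Mexican-Transition-Zone
Magnolia_vovidesii,"Jalisco, Mexico",Mexican-Transition-Zone
Magnolia_iltisiana,"Jalisco, Mexico",Mexican-Transition-Zone
Magnolia_panamensis,"Chiriqui, Panama",Mesoamerica
Magnolia_sharpii,"Chiapas, Mexico",Mesoamerica
Magnolia_grandis,"Kunming Botanical Garden, China",Asia
Magnolia_foveolata,"Kunming Botanical Garden, China",Asia
Magnolia_obovata,"Chollipo Arboretum, Rep. of Korea (native: Japan)",Asia
Magnolia_emarginata,"Centre, Haiti",Caribbean
Magnolia_splendens,"Puerto Rico",Caribbean
Magnolia_bankardiorum,"Zamora, Ecuador",Andes-North
Magnolia_coronata,"Antioquia, Colombia",Andes-North
Magnolia_jaenensis,"Cajamarca, Peru",Andes-North
Magnolia_ptaritepuiana,"Bolivar, Venezuela (tepui)",Brazil-Boreal
Magnolia_allenii,"Cocle, Panama",Mesoamerica
Magnolia_dodecapetala,"Magnolia Grove Arboretum, USA (native: Lesser Antilles)",Caribbean
Magnolia_kichuana,"Ecuador",Andes-North
Magnolia_lacandonica,"Chiapas, Mexico",Mesoamerica
Magnolia_macrocarpa,"Oaxaca, Mexico",Mesoamerica
Magnolia_mexicana,"Morelos, Mexico","Mesoamerica,Mexican-Transition-Zone"
Magnolia_ofeliae,"Jalisco, Mexico",Mexican-Transition-Zone
Magnolia_ovata,"Brazil","Brazil-Atlantic,Brazil-South"
Magnolia_pastazaensis,"Patuca, Ecuador",Andes-North
Magnolia_rimachii,"Loreto, Peru (western Amazonia)",Brazil-Boreal
Magnolia_silvioi,"Antioquia, Colombia",Pacific
Magnolia_virolinensis,"Virolin, Colombia",Andes-North
Magnolia_wetteri,"Puntarenas, Costa Rica",Mesoamerica
Magnolia_wolfii,"Pereira, Colombia",Pacific
Magnolia_zamorana,"Zamora Chinchipe, Ecuador",Andes-North
Magnolia_zoquepopolucae,"Veracruz, Mexico",Mexican-Transition-Zone
Magnolia_acuminata,"Chollipo Arboretum, Rep. of Korea (native: eastern N America)",Nearctic
Magnolia_biondii,"Chollipo Arboretum, Rep. of Korea (native: China)",Asia
Liriodendron_tulipifera,"Chollipo Arboretum, Rep. of Korea (native: eastern N America)",Nearctic
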