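ncols 20
nrows 20
xllcorner 0
yllcorner 0
cellsize 500
NODATA_value -9999
0.12235680894096512 0.43120435501035531 0.59835152369598488 0.55131864365799255 0.38440929337798235 0.2491047940737165 0.2002061356650576 0.19630532019657848 0.20681648803536767 0.23356635984546126 0.28233675584458617 0.32488828963691369 0.32063932192213729 0.30469691100960822 0.33290927222905919 0.35915878724850725 0.32580105853700875 0.28073022438581058 0.26094587348348286 0.1789262425643198
0.27803141770435474 0.62713000332534308 0.81697032833941075 0.78794121145323759 0.62006008103756649 0.46085426506033411 0.38350441070510816 0.35852434656508808 0.36276341718243227 0.409441445807678 0.49773552321573705 0.5791725692450761 0.61762794975784929 0.65420201059271987 0.70840489546673657 0.71327700335111688 0.65070391772633618 0.59405670457658144 0.54819045543166922 0.39352048555682501
0.36894835510811685 0.66803638549237188 0.82414097663975616 0.83522715638246081 0.73638637120951067 0.61938324088280661 0.55621175764543007 0.52158993036612888 0.4968491801341125 0.52487096560737567 0.62099455343408316 0.72436083198465395 0.79708915969950045 0.87289717215640727 0.92820000819761139 0.89266648326084053 0.80660310190200868 0.754189850308429 0.68496465182843003 0.46649623136826945
0.4359223387453241 0.67950954161052568 0.78771380186684403 0.81657348721947232 0.78553925875692365 0.73501199535304818 0.71723041829917833 0.70945823531311192 0.67819066605850109 0.65990038429244646 0.7101181436198416 0.80401932666947951 0.8800566006845979 0.93393691965987979 0.94122351109797409 0.86950486216778422 0.79168370320551729 0.76835210350111838 0.69675193544082026 0.4476452772450859
0.47478618305957171 0.71835651070300333 0.81761328352784557 0.83169860846700971 0.79887780242414552 0.75990677592568323 0.76103180369478796 0.80095158903026187 0.82460354551349002 0.80082331842273768 0.796354426543744 0.85347465331103933 0.89978874073989423 0.88662282394920611 0.82594718337370532 0.75409766393192967 0.73623150615716071 0.76641829632034497 0.70369956287859303 0.43908732548118518
0.4646046192079642 0.74633447522902363 0.88037531627195165 0.87342441973587714 0.78282350294219916 0.70243925217823111 0.69146332367240182 0.75751936812952025 0.85011916850091274 0.8887910772653087 0.88915121424896315 0.90539666375637107 0.89419005565399534 0.81642105655807506 0.71730181147495076 0.66967737852191056 0.71015985740493082 0.77673629830362523 0.71610805747415029 0.44117434676765976
0.41405626756335945 0.70759405501032424 0.85797099468201066 0.83228798361968626 0.70432208697096599 0.61421068215216068 0.60423961810646265 0.6599618167543182 0.7824091546774361 0.90964625274435207 0.97001313798936184 0.95891346545729184 0.88563104389836445 0.77774072040117193 0.68781240522054365 0.65311983087166625 0.68143941396554009 0.72774929197965399 0.67037820267323056 0.41684191116640074
0.32607137733198621 0.57186642171293678 0.68833176515557093 0.66450501369905512 0.58739375153054574 0.5708868665684248 0.5878123035326217 0.6104966043129616 0.72442570820648711 0.90593709638367348 1 0.94757082535838644 0.82209795300475419 0.72419777253510187 0.68793116918385111 0.6693855460593906 0.64616162015706258 0.63930706486133548 0.59178209121113723 0.38475029802167288
0.22975895930510523 0.41606664480333444 0.49313140459487642 0.50158666542445451 0.53031517336812883 0.61958927427205157 0.66818619432084558 0.65718709913250872 0.73798449471168082 0.90755194109709469 0.96591928803807936 0.84936394768810386 0.69475953387674516 0.6335488606469436 0.65997212424864771 0.6736123506315278 0.63446964065083333 0.59399714478703958 0.53993513266941384 0.35492860953085059
0.21895182309680006 0.39148642552783691 0.45127032276139223 0.47278050325717491 0.54477596466886369 0.67497822440165289 0.75015582906972988 0.74341343898372692 0.78664830821158449 0.88774125549628646 0.88341020923674463 0.74409947319795944 0.61420140743218044 0.58856073966029421 0.63333508848987241 0.66511676326560698 0.65497064872268107 0.62234488913693486 0.54531262104980327 0.34268058401911711
0.29615784499511605 0.48808320854445203 0.53677830856264508 0.52476458020261807 0.54833415141718644 0.64863430819240975 0.75589307290389751 0.79680774260945431 0.80497515978135492 0.80963578716973683 0.76734956297223778 0.68666604823012434 0.63477701848981327 0.63221018445608546 0.65799253075759256 0.687499058320857 0.71194827018795814 0.70639649820098638 0.61074732906628904 0.37248730401894981
0.35481700184819265 0.54473528565131302 0.56896386313433134 0.52059571677916661 0.49914675541343817 0.56982016537534663 0.69496642781102347 0.7652864279625855 0.73986050691015526 0.67531041629457655 0.64026632129040351 0.65350723400806998 0.68243225778123717 0.69873129761019037 0.72251374358726539 0.76919865989744551 0.81631389235696772 0.80996079913638996 0.68693425898968274 0.41551336553572266
0.35484227244733235 0.50488660293384446 0.49386136446338735 0.44951594030862357 0.4485999029036315 0.51289508826658825 0.60785879887880212 0.65281095930891497 0.61684282026694859 0.56037254775427148 0.56607614874112244 0.63630599076071792 0.69738209039332821 0.72318654113324032 0.77121181032269237 0.86113070159547822 0.92098756589661446 0.87695864795751965 0.71221645146119916 0.42491431509295885
0.33600211315911077 0.45205965040348112 0.43758679362871727 0.4476086798588565 0.50074785945648614 0.54937348685508092 0.5772293722956493 0.57782224400002269 0.56733879946460775 0.57834971519040657 0.62873470854012115 0.69316514762732595 0.71699752372753933 0.71192065442866381 0.75809158623862538 0.86207437232757367 0.91630179173963833 0.84001752768994709 0.6516900438551928 0.36996248007645677
0.32652423384291279 0.45332793489018158 0.48779177448942185 0.57002263371179851 0.65360670627237305 0.66166835198243734 0.62907374408747063 0.6141270198848906 0.64849324385058693 0.72303362584871833 0.79865972628241488 0.82780364453320954 0.77472612063659974 0.6899296449984339 0.68168046648162561 0.75619631260245401 0.79669133273083215 0.71428924338345767 0.52224889422965604 0.25298073153362782
0.31174389613469922 0.49348106223398036 0.59042091811879827 0.69851899120970107 0.76190396152819317 0.73190063581116704 0.68592091786691378 0.69759595626882387 0.76862157558929145 0.85831876666089568 0.92381380298113169 0.92615957950860717 0.83133940618452817 0.68509247739375267 0.61724286656993788 0.66210213936342244 0.6976985743202303 0.60977577031230301 0.40327866761775816 0.13798698339935553
0.28264318869344407 0.53729995075809456 0.67850123899976733 0.76210472475916857 0.78329144261231931 0.73923648573353129 0.71321818887995669 0.76201703270484722 0.84961621812557087 0.91553030439265293 0.93695798466363089 0.91901770243812608 0.84553315939640317 0.71672767728216447 0.64127918979693221 0.67665265973793987 0.69711128342497553 0.58377348013712582 0.36240716420250368 0.10401961459718706
0.27450420146495635 0.58771938974985216 0.75544656265720822 0.80984090878224313 0.79790698498251156 0.74127582509524048 0.71226930833801749 0.77151842416443184 0.86949145234921832 0.90975074190592564 0.87360844191796916 0.81933182308202157 0.77096596396829054 0.70421836256208659 0.67999416206319963 0.72457873065794587 0.70751477973150867 0.56364008027477763 0.3614587176755103 0.13389877714502676
0.2808156034193805 0.6064639323835036 0.77305158955167208 0.79797696947595975 0.75080764251816834 0.66699028117320913 0.60913174234887779 0.65499715784086388 0.75993047785497225 0.78978772579958056 0.71834705492210993 0.62590260244294471 0.56484036775905855 0.54273053220150891 0.59071410972541061 0.66000053998019559 0.61269804912550918 0.45914522586395295 0.30061865851545438 0.11981768186419228
0.18954633684491798 0.45117791307256755 0.5764104253027782 0.57354432290454349 0.50472954830052441 0.41178617572866283 0.34398109863863818 0.37070297080439746 0.45844220152488641 0.48370088596435717 0.4224805721586874 0.33146937251078396 0.25679025105710196 0.24942207534677446 0.3345355367375189 0.4168471446191751 0.37116676116126163 0.24295806396652192 0.12958191140220876 0
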